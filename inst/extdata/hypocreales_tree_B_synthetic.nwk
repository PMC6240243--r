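((((((Hmin:29,Hsin:29):36,Htho:65):45,Mrob:110):35,(((Tatr:35,Tvir:35):50,Trei:85):45,(Fgra:60,Fsol:60):70):15):20,Cros:165):10,Ncra:175);
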