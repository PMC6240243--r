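# Codon-state machinery for the site-selection scan and simulator:
# universal genetic code, MG94-style rate decomposition (synonymous rate
# proportional to the dS class, nonsynonymous to the dN class) crossed with
# a reversible nucleotide exchangeability pattern in which A-C, A-G and C-G
# rates are fixed to 1 and the transversions to T (R_AT, R_CT, R_GT) are
# free, with F3x4 codon frequencies.

NT <- c("A", "C", "G", "T")

genetic_code_table <- function() {
  # universal genetic code, codons in ACGT-lexicographic order
  codons <- character(64)
  i <- 0L
  for (a in NT) for (b in NT) for (c in NT) {
    i <- i + 1L
    codons[i] <- paste0(a, b, c)
  }
  std <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
           ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
           TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
           ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
           TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
           AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
           TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
           AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  setNames(unname(std[codons]), codons)
}

sense_codons <- function() {
  gc <- genetic_code_table()
  names(gc)[gc != "*"]
}

# pairwise single-nucleotide-change structure over the 61 sense codons
codon_pair_info <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cods <- sense_codons()
    gc <- genetic_code_table()
    n <- length(cods)
    mat <- matrix(strsplit(paste(cods, collapse = ""), "")[[1]], n, 3,
                  byrow = TRUE)
    pair_id <- matrix(0L, n, n)      # 1..6 = AC AG AT CG CT GT; 0 = no
    synon <- matrix(FALSE, n, n)
    target_nt <- matrix(0L, n, n)    # nt index of target base
    target_pos <- matrix(0L, n, n)   # codon position of the change
    pair_names <- c("AC", "AG", "AT", "CG", "CT", "GT")
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(mat[i, ] != mat[j, ])
      if (length(diff) != 1L) next
      a <- mat[i, diff]; b <- mat[j, diff]
      pr <- paste(sort(c(a, b)), collapse = "")
      pair_id[i, j] <- match(pr, pair_names)
      synon[i, j] <- gc[cods[i]] == gc[cods[j]]
      target_nt[i, j] <- match(b, NT)
      target_pos[i, j] <- diff
    }
    cache <<- list(codons = cods, mat = mat, pair_id = pair_id,
                   synon = synon, target_nt = target_nt,
                   target_pos = target_pos)
    cache
  }
})

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies (three positions x four bases)
#' multiplied out over the 61 sense codons and renormalized.
#'
#' @param codon_alignment a `codon_alignment`.
#' @return list with `pos_freqs` (3 x 4) and `pi_codon` (length 61).
#' @export
f3x4_frequencies <- function(codon_alignment) {
  ncod <- ncol(codon_alignment) / 3
  pos_freqs <- matrix(0, 3, 4, dimnames = list(NULL, NT))
  for (p in 1:3) {
    cols <- seq(p, ncol(codon_alignment), by = 3)
    chars <- as.vector(codon_alignment[, cols])
    chars <- chars[chars %in% NT]
    tab <- table(factor(chars, levels = NT))
    # pseudo-count guards degenerate alignments with absent bases
    pos_freqs[p, ] <- (as.numeric(tab) + 0.5) / (sum(tab) + 2)
  }
  f3x4_from_pos(pos_freqs)
}

f3x4_from_pos <- function(pos_freqs) {
  info <- codon_pair_info()
  pi_codon <- apply(info$mat, 1, function(cod) {
    pos_freqs[1, cod[1]] * pos_freqs[2, cod[2]] * pos_freqs[3, cod[3]]
  })
  pi_codon <- pi_codon / sum(pi_codon)
  list(pos_freqs = pos_freqs, pi_codon = pi_codon)
}

# synonymous and nonsynonymous rate-structure matrices, jointly normalized
# so that Q = 1*Qs + 1*Qn has one expected substitution per codon per unit
# time at equilibrium; then Q(alpha, beta) = alpha*Qs + beta*Qn.
mg94_structure <- function(R, pos_freqs) {
  stopifnot(length(R) == 3, all(R > 0))
  info <- codon_pair_info()
  rho <- c(1, 1, R[1], 1, R[2], R[3]) # AC AG AT CG CT GT
  freqs <- f3x4_from_pos(pos_freqs)
  pi_codon <- freqs$pi_codon
  n <- length(info$codons)
  base <- matrix(0, n, n)
  sel <- info$pair_id > 0
  base[sel] <- rho[info$pair_id[sel]] *
    pos_freqs[cbind(info$target_pos[sel], info$target_nt[sel])]
  qs <- base * info$synon
  qn <- base * (!info$synon)
  full <- qs + qn
  diag(full) <- -rowSums(full)
  rate <- -sum(pi_codon * diag(full))
  list(qs = qs / rate, qn = qn / rate, pi_codon = pi_codon)
}

mg94_q <- function(structure, alpha, beta) {
  q <- alpha * structure$qs + beta * structure$qn
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  q
}

# codon alignment -> sites x sequences matrix of sense-codon indices
# (NA for codons containing gaps or ambiguity: treated as missing data)
codon_index_matrix <- function(codon_alignment) {
  cods <- sense_codons()
  nsite <- ncol(codon_alignment) / 3
  out <- matrix(NA_integer_, nsite, nrow(codon_alignment),
                dimnames = list(NULL, rownames(codon_alignment)))
  for (i in seq_len(nrow(codon_alignment))) {
    for (s in seq_len(nsite)) {
      cod <- paste(codon_alignment[i, (3 * s - 2):(3 * s)], collapse = "")
      out[s, i] <- match(cod, cods)
    }
  }
  out
}
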