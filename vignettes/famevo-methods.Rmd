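---
title: "Models and methods behind famevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

famevo packages five analysis stages that together characterize how a gene
family — fungal subtilisin-like serine proteases are the motivating case —
evolves across a clade: changes in family *size* on a dated species tree,
the *events* (duplications and losses) visible in gene trees, the regions
of the protein where paralog groups have *diverged* in constraint,
individual codon sites under *positive selection*, and the *expression*
response of family members measured by RT-qPCR. This vignette documents the
models, the defaults and why they hold, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The dated species tree

All time-based analyses run on a rooted, ultrametric species tree with
branch lengths in million years (Myr). `calibrate_tree()` rescales a
relative-time ultrametric tree by a single factor so that a named split
sits at an absolute age — the package's fixtures pin the
*Hirsutella minnesotensis* / *H. sinensis* split at 29 Myr, following the
fossil calibration used for Hypocreales. Trees that are not ultrametric
within a relative tolerance of 1e-6 on tip depths are rejected rather than
silently stretched: a miscalibrated input should fail loudly.

The two bundled 11-taxon trees (`hypocreales_tree_path()`) carry the two
published alternative placements of *Clonostachys rosea* (sister to the
*Fusaria*, or basal in Hypocreales). Their topologies follow the
literature; their branch lengths are **synthetic** — plausible Myr values
consistent with the 29-Myr calibration — because no machine-readable
chronogram is available. They are fixtures for simulation and testing, not
published estimates, and are labelled `_synthetic` accordingly.

## Family-size evolution: the single-rate birth--death model

Family size evolves as a linear birth--death process in which every gene
copy is independently duplicated or lost at the same rate $\lambda$ (per
gene per Myr). With $\alpha = \lambda t/(1+\lambda t)$, the transition
probability along a branch of duration $t$ is

$$P(c \mid s) = \sum_{k=0}^{\min(s,c)} \binom{s}{k}\binom{s+c-k-1}{s-1}
  \alpha^{s+c-2k}(1-2\alpha)^k,$$

with size 0 absorbing. Numerically this closed form is only evaluated
where it is stable ($\lambda t \le 1$, where every term is positive). For
matrices and for longer branches the package uses the fact that the
process restricted to sizes $1..C$ is similar to a symmetric tridiagonal
matrix under the diagonal scaling $1/\sqrt{n}$: one cached
eigendecomposition per cap $C$ yields the transition block for any
$(\lambda, t)$ in two dense products, and the extinction column is exactly
$\alpha^s$. Transition matrices carry 60 states of headroom above the cap
so that within-branch excursions beyond the largest observed count do not
bias the returned probabilities; tests pin the kernel against an
independent matrix exponential of the generator.

Families enter the analysis when they have at least 2 genes in some
species and are present in at least 2 species; the likelihood of a
family's tip counts is computed by Felsenstein pruning over the kernel
with all internal sizes marginalized. Choices a user should know:

* **Count cap**: `2 * max observed count + 10`. Doubling the largest
  count leaves ample room for ancestral states above the observed range.
* **Root prior**: uniform over $1..C$ — a root size of 0 is excluded
  because an observed family existed at the root. A flat prior is the
  least informative choice that is still proper and testable.
* **$\lambda$ estimation**: bounded one-dimensional maximum likelihood
  (`optimize`), summed over families. An all-constant table returns
  $\hat\lambda = 0$ with a boundary flag.
* **Family p-value**: a Monte Carlo likelihood-ranking null. `n_null`
  families are simulated from the fitted model (root from the prior,
  exact branch transitions) and the p-value is the fraction with
  log-likelihood at or below the observed one, with a +1 pseudo-count so
  p is never 0. Because the null log-likelihood sample depends only on
  the model, the batch interface shares one null sample across families;
  the distribution is identical and the cost drops by a factor of the
  family count. Calibration is verified: under the fitted model the
  rejection rate at 0.05 lands in [0.03, 0.07] and the p-values are
  near-uniform.
  A known limitation follows from the flat root prior: the null
  log-likelihood distribution is wide (large simulated roots diffuse into
  many tip configurations), so the family test is well calibrated but has
  power mainly against families whose pattern is broadly incompatible
  with any single-rate birth--death history (strong independent swings
  across several lineages), not against a single moderate jump on one
  branch. Single-branch events are the job of the per-branch tail tests
  below.
* **Branch calls**: ancestral sizes are max-posterior states from the
  up--down (outside) algorithm, ties going to the *smaller* count (a
  conservative choice that never invents genes); each branch gets a
  two-sided exact tail test of its parent-to-child change, flagged only
  inside families already significant at 0.05. No cross-branch multiple
  testing correction is applied by default — the per-lineage flags mirror
  how such analyses are conventionally reported — but a
  Benjamini--Hochberg option exists (`bh_correct`).

## Duplication--loss reconciliation

`lca_reconcile()` implements the classical last-common-ancestor mapping:
each gene-tree node maps to the species-tree LCA of its descendant tips'
species; a node is a duplication exactly when its mapping equals a
child's mapping; and each species node silently passed between a parent
and child mapping contributes one loss, attributed to the branch of the
lineage that failed to appear. The LCA mapping provably minimizes the
duplication count, and tests confirm the weighted cost
$1.5D + 1L$ (the conventional duplication/loss weighting) equals a
brute-force dynamic-programming minimum over all valid reconciliations —
exhaustively for all 3-leaf gene trees over a 4-taxon species tree and on
seeded samples at 4--6 leaves (full enumeration at 6 leaves is
combinatorially out of reach of a test budget; the sampled check covers
the same code paths).

Edges with bootstrap support below 90% are collapsed into polytomies by
`rearrange_weak_edges()` and re-resolved to minimize cost: exhaustively
for polytomies of degree at most 6 (945 rooted resolutions), greedily —
joining the pair of children whose species mapping is deepest — beyond.
The original resolution is always kept as a candidate, so the reported
cost never exceeds the input's. Losses above the species root are not
counted (there is no information above the root); conventions differ on
this point, so it is stated here explicitly.

## Reverse conservation analysis

Per-column evolutionary rates are empirical-Bayes posterior means under a
fixed JTT exchangeability matrix with a discretized gamma(α = 1) prior
over 16 rate categories:
$S_c = \sum_k r_k L_c(r_k) \pi_k / \sum_k L_c(r_k) \pi_k$, computed by
pruning per category. High $S$ means poorly conserved. The guide tree is
user-supplied; absent one, a neighbor-joining tree on identity-fraction
distances is built as declared plumbing (the scores are a profiling
heuristic, not a phylogenetic estimate). Columns gapped in more than half
of the sequences are excluded *before* normalization; exactly half is
kept.

Scores are z-normalized over included columns with the **population**
standard deviation (so mean is exactly 0 and sd exactly 1, to 1e-9 — a
bit-reproducibility choice) and smoothed with a centered 7-column moving
average over included columns, truncated at the profile edges (the first
included column averages included columns 1--4). Maximal runs with
W mean ≥ 0.5 become variable regions; runs separated by fewer than 3
included columns merge (`min_gap`, an artifact knob recorded in the run
manifest — the merging rule behind published region counts is not
recoverable, so it is explicit here). Regions are reported in 1-based
inclusive residue coordinates of a named reference sequence.

Two paralog groups are compared by profiling each group's own alignment
separately (normalization is within-group; whether joint normalization
was ever intended is unknowable, and within-group is the choice that
makes the two profiles independently interpretable) and mapping both onto
the shared reference. Every variable region from either group is
classified by the two-group rule on region-mean W: ≥ 0.5 in one group and
< 0.5 in the other is a functional-divergence call; both high is
variable-in-both; both low, conserved-in-both. Zero-variance profiles
(e.g. identical sequences) are flagged degenerate, score 0 everywhere,
and yield no regions.

## Site-wise selection: the REL codon scan

The codon model is MG94-style: single-nucleotide codon exchanges at rate
proportional to a synonymous class value $\alpha$ (dS) or nonsynonymous
class value $\beta$ (dN), times the nucleotide exchangeability of the
changed base pair, times the F3x4 positional frequency of the target
base. The nucleotide pattern fixes A–C, A–G and C–G at 1 and leaves
R\_AT, R\_CT, R\_GT free. Site-to-site variation is a random effect: dS
and dN each take $K=3$ free values with free weights, crossed into a
9-cell grid. Three classes per axis is the smallest grid that can express
"below, at, and above" the synonymous rate, which is all the
positive-selection posterior needs; grid size is recorded in the model
output.

Fitting alternates (i) closed-form EM updates of the product weights,
which are monotone in likelihood, with (ii) Nelder--Mead blocks for
(branch scale, R parameters) and for the class values, each started at
the current point so it can only improve; dS values are renormalized to
mean 1 after each sweep, with the factor absorbed into the branch scale
(the two are otherwise confounded). The outer loop asserts a
non-decreasing log-likelihood at every iteration and stops when the gain
drops below `tol` (1e-6) or at `max_iter`. Three jittered restarts are
the default; the test and acceptance runs use one restart and two outer
iterations at 300--500 codons on 6-taxon trees — problem sizes chosen so
the full property suite exercises 40+ fits — which is ample for the
calibration and ranking properties they assert (weights and Bayes-factor
ranking stabilize within the first couple of sweeps; the remaining
iterations polish parameter values).

Per site, the empirical-Bayes posterior over the grid gives
$PP = P(\mathrm{dN} > \mathrm{dS} \mid \mathrm{site})$ and the Bayes
factor is the posterior/prior odds ratio of that event (0 when the prior
positive mass is 0; infinite when the posterior is 1 with prior mass
below 1). Classification: BF⁺ ≥ 50 strong positive; 10 ≤ BF⁺ < 50 weak;
BF⁻ ≥ 50 (the symmetric factor for dN < dS, at the same threshold — the
negative-selection criterion is not separately documented anywhere
authoritative, so symmetry is the declared choice) and not positive is
negative; neutral otherwise. Gapped or ambiguous codons are missing data,
marginalized in the pruning; internal stop codons are rejected at input.

## Expression analysis

Relative expression uses the 2^−ΔΔCt method against a reference gene
(tubulin in the motivating assays): technical replicates are averaged
into one Ct per biological replicate first; ΔCt = Ct_target −
Ct_reference; ΔΔCt subtracts the mean control ΔCt. Statistics run on the
log2 scale (ΔΔCt), where qPCR noise is closest to homoscedastic, and
reported means are back-transformed — geometric means — so the control is
exactly 1 by construction. Amplification is assumed ideal (factor 2);
primer efficiencies from dilution series are computed and reported as QC
(`primer_efficiency()`: factor $10^{-1/\mathrm{slope}}$) but do not enter
the ΔΔCt formula, matching standard practice. "No detectable expression"
(N/D) is a first-class state: excluded from the per-gene ANOVA, printed
as N/D, never imputed as a large Ct. Replicate exclusion is explicit and
logged — no automatic outlier rejection. Per gene, a one-way ANOVA
provides the pooled MSE for Fisher LSD pairwise tests at α = 0.05, and
compact letters are assigned greedily from the highest mean over maximal
mutually non-significant runs (the familiar transitivity caveat of letter
displays applies and is deliberate). At least 3 biological replicates per
treatment are required; treatments below that are flagged, and genes with
fewer than 2 usable treatments skip statistics with a flag. No
multiple-testing correction is applied across genes, matching per-gene
LSD reporting.

## The synthetic-data generators

Each generator is a pure function of its arguments and a seed (all
sub-streams derive from one master seed via a counter scheme), and each
emits a manifest with the complete ground truth needed to score its
downstream stage:

* `simulate_family_counts()`: exact event-driven (Gillespie) birth--death
  along every branch; default root prior uniform on 1--10 genes (typical
  protease subfamily sizes). Single-branch transition frequencies are
  cross-validated against the analytic kernel.
* `simulate_gene_tree()`: gene lineages duplicate and die inside the
  species tree; unpruned duplications are recorded per species branch.
  With losses off, the recorded count is exactly what reconciliation
  must recover.
* `simulate_region_alignment()`: JTT evolution with per-column rate
  multipliers in planted blocks.
* `simulate_codon_alignment()`: MG94-style evolution with per-site
  (dN, dS) classes in stated fractions.
* `simulate_ct_table()`: reference Ct ~ Normal(20, σ), target offset by a
  baseline ΔCt of 3 cycles minus log2(fold change), with independent
  Gaussian noise; σ = 0.15 is a realistic plate noise level and the
  default in recovery tests.

What they do **not** emulate — and therefore what passing tests cannot
certify about real data: annotation and gene-model errors in family
counts; alignment error and among-site compositional heterogeneity beyond
rate multipliers; recombination or gene conversion between paralogs;
selection regimes that vary across branches; correlated technical
structure in qPCR plates. The property suite demonstrates that each
method recovers what its own generative model plants, at the stated
sizes; real-data performance additionally depends on how far reality
departs from those models.

## Problem sizes and runtime choices

The default verification sizes are: 500 families on the 11-taxon tree for
rate recovery and p-value calibration (n_null = 1000); 20 seeds of
planted-block alignments (400 columns, 10 taxa, 4x contrast) for the
conservation scan; 20 neutral and 20 planted selection fits (300--500
codons, 6 taxa); 20 simulated gene trees for reconciliation recovery.
These are the package's verification conditions, chosen to make
stochastic pass/fail boundaries comfortably stable under reseeding.
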