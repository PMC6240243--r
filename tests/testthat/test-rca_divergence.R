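test_that("gap masking uses the strict majority rule", {
  rows <- c(rep("MKV", 4), rep("M-V", 6)) # column 2: 6/10 gaps
  aln <- as_alignment(setNames(rows, paste0("s", 1:10)))
  expect_equal(mask_gappy_columns(aln), c(TRUE, FALSE, TRUE))
  rows2 <- c(rep("MKV", 5), rep("M-V", 5)) # exactly half: kept
  aln2 <- as_alignment(setNames(rows2, paste0("s", 1:10)))
  expect_true(all(mask_gappy_columns(aln2)))
  aln3 <- as_alignment(c(a = "MKV", b = "MRV"))
  expect_true(all(mask_gappy_columns(aln3)))
})

test_that("site rates order invariant below variable columns", {
  tr <- rca_test_tree(8)
  sim <- simulate_region_alignment(tr, 60,
                                   data.frame(start = 31, end = 60,
                                              rate_multiplier = 8),
                                   seed = 5)
  raw <- site_rates(sim$alignment, tr)
  # an invariant column scores strictly below a maximally variable one
  aln <- sim$alignment
  invariant_cols <- which(apply(aln, 2, function(x) length(unique(x)) == 1))
  varied_cols <- which(apply(aln, 2, function(x) length(unique(x)) >= 6))
  if (length(invariant_cols) && length(varied_cols)) {
    expect_lt(max(raw[invariant_cols]), min(raw[varied_cols]))
  }
  # identical sequences: identical columns score identically and the
  # zero-variance profile is flagged degenerate (scores set to 0)
  same <- as_alignment(setNames(rep("MMMMM", 4), paste0("s", 1:4)))
  tr4 <- ape::read.tree(text = "((s1:0.1,s2:0.1):0.1,(s3:0.1,s4:0.1):0.1);")
  raw_same <- site_rates(same, tr4)
  expect_equal(diff(range(raw_same)), 0, tolerance = 1e-10)
  prof <- normalize_and_window(raw_same)
  expect_true(prof$degenerate)
  expect_true(all(prof$columns$norm_s == 0))
  expect_equal(nrow(call_variable_regions(prof)), 0)
  expect_error(site_rates(same, rca_test_tree(8)), "do not match")
})

test_that("3-taxon posterior mean rate matches direct summation", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.35,c:0.5);")
  aln <- as_alignment(c(a = "MKVA", b = "MRVA", c = "MKLC"))
  k <- 4
  raw <- site_rates(aln, tr, n_rate_categories = k, alpha = 1)
  md <- famevo:::aa_model_data("JTT")
  q <- famevo:::make_q_matrix(md$exchangeability, md$pi)
  fac <- famevo:::pmat_factory(q, md$pi)
  rates <- phangorn::discrete.gamma(1, k)
  trp <- stats::reorder(tr, "postorder")
  for (col in 1:4) {
    liks <- vapply(rates, function(r) {
      Ps <- lapply(trp$edge.length, function(t) fac(r * t))
      tot <- 0
      for (x in 1:20) {
        pr <- md$pi[x]
        for (e in seq_len(nrow(trp$edge))) {
          tipchar <- aln[trp$tip.label[trp$edge[e, 2]], col]
          pr <- pr * Ps[[e]][x, match(tipchar, md$states)]
        }
        tot <- tot + pr
      }
      tot
    }, numeric(1))
    expect_equal(raw[col], sum(rates * liks) / sum(liks),
                 tolerance = 1e-10)
  }
})

test_that("normalization and windowing follow the declared conventions", {
  prof <- normalize_and_window(c(1, 2, 3), n = 1)
  expect_equal(prof$columns$norm_s, c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-4)
  expect_equal(prof$columns$norm_s[1], -1.2247, tolerance = 1e-4)
  # population sd: mean 0, sd 1 to 1e-9
  set.seed(8)
  raw <- runif(200)
  mask <- runif(200) > 0.2
  p2 <- normalize_and_window(raw, mask)
  z <- p2$columns$norm_s[p2$columns$included]
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  # constant normalized series gives a constant W mean
  expect_true(all(abs(normalize_and_window(rep(2, 10))$columns$w_mean) <
                    1e-12))
  # edge policy: first window averages included columns 1..4
  p3 <- normalize_and_window(raw, mask, n = 7)
  z3 <- p3$columns$norm_s[p3$columns$included]
  w3 <- p3$columns$w_mean[p3$columns$included]
  expect_equal(w3[1], mean(z3[1:4]))
  expect_equal(w3[10], mean(z3[7:13]))
  # monotone under uniform shifts of the raw score
  p4 <- normalize_and_window(raw + 5, mask)
  expect_equal(p4$columns$w_mean, p3$columns$w_mean, tolerance = 1e-9)
})

test_that("variable region calling thresholds, merges, and maps coordinates", {
  # craft a profile via raw scores that z-normalize predictably
  raw <- rep(0, 40)
  raw[10:16] <- 10
  raw[20:24] <- 10
  prof <- normalize_and_window(raw, n = 1)
  regs <- call_variable_regions(prof, I = 0.5, min_gap = 3)
  expect_equal(nrow(regs), 2)
  # runs separated by < 3 included columns merge
  raw2 <- rep(0, 40)
  raw2[10:13] <- 10
  raw2[16:19] <- 10 # gap of 2 columns (14, 15)
  prof2 <- normalize_and_window(raw2, n = 1)
  regs2 <- call_variable_regions(prof2, I = 0.5, min_gap = 3)
  expect_equal(nrow(regs2), 1)
  expect_equal(c(regs2$start_col, regs2$end_col), c(10, 19))
  # all below threshold: empty
  expect_equal(nrow(call_variable_regions(normalize_and_window(rep(0, 10)))),
               0)
  # reference coordinates flow through the map
  aln <- as_alignment(setNames(rep(paste(rep("A", 40), collapse = ""), 3),
                               c("ref", "b", "c")))
  prof3 <- normalize_and_window(raw2, n = 1, map = map_to_reference(aln,
                                                                    "ref"))
  regs3 <- call_variable_regions(prof3, I = 0.5, min_gap = 3)
  expect_equal(c(regs3$start, regs3$end), c(10, 19))
})

test_that("planted high-rate blocks are recovered and calls are stable", {
  tr <- rca_test_tree(10)
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_region_alignment(tr, 400,
                                     data.frame(start = 181, end = 200,
                                                rate_multiplier = 4),
                                     seed = 100 + s)
    raw <- site_rates(sim$alignment, tr)
    prof <- normalize_and_window(raw, mask_gappy_columns(sim$alignment))
    regs <- call_variable_regions(prof)
    if (nrow(regs) &&
          max(mapply(interval_jaccard, regs$start_col, regs$end_col,
                     181, 200)) >= 0.6) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 4)
  # region calls invariant to relabeling of sequences
  sim <- simulate_region_alignment(tr, 200,
                                   data.frame(start = 101, end = 120,
                                              rate_multiplier = 4),
                                   seed = 55)
  aln <- sim$alignment
  raw1 <- site_rates(aln, tr)
  perm <- sample(nrow(aln))
  aln2 <- aln[perm, , drop = FALSE]
  tr2 <- tr
  expect_equal(site_rates(aln2, tr2), raw1, tolerance = 1e-10)
})

test_that("two-group divergence classification follows the I rule", {
  mk_prof <- function(w_target, ref_len = 30) {
    # raw scores engineered so the unsmoothed profile has the wanted W
    raw <- w_target
    aln <- as_alignment(setNames(rep(paste(rep("A", ref_len), collapse = ""),
                                     2), c("ref", "x")))
    normalize_and_window(raw, n = 1, map = map_to_reference(aln, "ref"))
  }
  base <- c(rep(0, 10), rep(10, 8), rep(0, 12))
  # one strong downward outlier: bulk z stays ~0.19, never crossing I,
  # so this profile has no variable region of its own
  flat <- c(rep(1, 29), -100)
  pa <- mk_prof(base)
  pb <- mk_prof(flat)
  calls <- call_divergent_regions(pa, pb, I = 0.5)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$class, "divergent-in-A")
  expect_equal(c(calls$start, calls$end), c(11, 18))
  # both high: variable-in-both, not a divergence call
  calls2 <- call_divergent_regions(pa, mk_prof(base), I = 0.5)
  expect_equal(calls2$class, "variable-in-both")
  # symmetric direction
  calls3 <- call_divergent_regions(pb, pa, I = 0.5)
  expect_equal(calls3$class, "divergent-in-B")
  # simulated pair: planted block in A only
  tr <- rca_test_tree(10)
  simA <- simulate_region_alignment(tr, 200,
                                    data.frame(start = 101, end = 120,
                                               rate_multiplier = 6),
                                    seed = 9)
  simB <- simulate_region_alignment(tr, 200, NULL, seed = 10)
  ref_aln <- function(sim) {
    aln <- sim$alignment
    rownames(aln)[1] <- "ref"
    aln
  }
  alnA <- ref_aln(simA); alnB <- ref_aln(simB)
  trA <- tr; trA$tip.label[trA$tip.label == rownames(simA$alignment)[1]] <- "ref"
  profA <- normalize_and_window(site_rates(alnA, trA),
                                mask_gappy_columns(alnA),
                                map = map_to_reference(alnA, "ref"))
  profB <- normalize_and_window(site_rates(alnB, trA),
                                mask_gappy_columns(alnB),
                                map = map_to_reference(alnB, "ref"))
  calls4 <- call_divergent_regions(profA, profB)
  in_a <- calls4[calls4$class == "divergent-in-A", ]
  expect_gte(nrow(in_a), 1)
  expect_gte(max(mapply(interval_jaccard, in_a$start, in_a$end, 101, 120)),
             0.5)
})
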