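test_that("grid likelihood matches 3-taxon enumeration", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.4,c:0.2);")
  sim <- simulate_codon_alignment(tr, 15,
                                  data.frame(fraction = 1, dN = 0.5, dS = 1),
                                  list(R = c(2, 1.5, 0.8)), seed = 5)
  idx <- famevo:::codon_index_matrix(sim$alignment)
  pos <- matrix(0.25, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  st <- famevo:::mg94_structure(c(2, 1.5, 0.8), pos)
  cells <- famevo:::rel_cells(c(0.5, 1.5), c(0.25, 1.2))
  trp <- stats::reorder(tr, "postorder")
  idx <- idx[, trp$tip.label]
  partials <- lapply(1:3, function(i) {
    m <- matrix(0, nrow(idx), 61)
    m[cbind(seq_len(nrow(idx)), idx[, i])] <- 1
    m
  })
  cl <- famevo:::rel_site_cell_loglik(trp, partials, st, cells, 1)
  for (g in seq_len(nrow(cells))) {
    q <- famevo:::mg94_q(st, cells$ds[g], cells$dn[g])
    fac <- famevo:::pmat_factory(q, st$pi_codon)
    Ps <- lapply(trp$edge.length, fac)
    for (s in seq_len(nrow(idx))) {
      tot <- 0
      for (x in 1:61) {
        pr <- st$pi_codon[x]
        for (e in 1:3) pr <- pr * Ps[[e]][x, idx[s, trp$edge[e, 2]]]
        tot <- tot + pr
      }
      expect_equal(cl[s, g], log(tot), tolerance = 1e-10)
    }
  }
})

test_that("identical sequences drive the likelihood to the frequency limit", {
  seqs <- setNames(rep(strrep("ATGGCT", 10), 4), paste0("s", 1:4))
  aln <- as_alignment(seqs, type = "codon")
  tr <- ape::read.tree(text = "((s1:0.1,s2:0.1):0.1,(s3:0.1,s4:0.1):0.1);")
  idx <- famevo:::codon_index_matrix(aln)
  freqs <- f3x4_frequencies(aln)
  st <- famevo:::mg94_structure(c(1, 1, 1), freqs$pos_freqs)
  trp <- stats::reorder(tr, "postorder")
  partials <- lapply(seq_len(ncol(idx)), function(i) {
    m <- matrix(0, nrow(idx), 61)
    m[cbind(seq_len(nrow(idx)), idx[, i])] <- 1
    m
  })
  # at a vanishing branch scale each site's likelihood is its codon's
  # equilibrium frequency
  cl <- famevo:::rel_site_cell_loglik(trp, partials,
                                      st, data.frame(ds = 1, dn = 1), 1e-12)
  expect_equal(as.vector(cl), log(st$pi_codon[idx[, 1]]), tolerance = 1e-6)
})

test_that("REL fit increases the likelihood monotonically and converges", {
  tr <- rel_test_tree(5)
  sim <- simulate_codon_alignment(tr, 120,
                                  data.frame(fraction = 1, dN = 0.4, dS = 1),
                                  list(R = c(1.5, 1.2, 0.9)), seed = 31)
  fit <- fit_rel_model(sim$alignment, tr, n_restarts = 1, max_iter = 3,
                       opt_maxit = 10)
  expect_true(all(diff(fit$trace) >= -1e-6))
  expect_equal(sum(fit$ds_weights), 1, tolerance = 1e-9)
  expect_equal(sum(fit$dn_weights), 1, tolerance = 1e-9)
  expect_true(all(fit$R > 0))
  # mean dS constrained to 1 for identifiability
  expect_equal(sum(fit$ds_weights * fit$ds_values), 1, tolerance = 1e-8)
  expect_error(fit_rel_model(sim$alignment[1:2, ], tr), "at least 3")
})

test_that("purifying simulations put the prior weight on dN < dS", {
  tr <- rel_test_tree(5)
  frac <- numeric(3)
  for (s in 1:3) {
    sim <- simulate_codon_alignment(tr, 150,
                                    data.frame(fraction = 1, dN = 0.2,
                                               dS = 1),
                                    list(R = c(1.2, 1.1, 1)), seed = 200 + s)
    fit <- fit_rel_model(sim$alignment, tr, n_restarts = 1, max_iter = 2,
                         opt_maxit = 10)
    cells <- expand.grid(ds = fit$ds_values, dn = fit$dn_values)
    w <- as.vector(outer(fit$ds_weights, fit$dn_weights))
    frac[s] <- sum(w[cells$dn < cells$ds])
  }
  expect_gte(median(frac), 0.9)
})

test_that("Bayes factors follow the posterior/prior odds definition", {
  expect_equal(famevo:::bayes_factor(0.5, 1 / 9), 8)
  expect_equal(famevo:::bayes_factor(c(0, 1), 0.2), c(0, Inf))
  expect_equal(famevo:::bayes_factor(0.7, 0), 0)
  # BF strictly increasing in PP at fixed prior
  pps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(famevo:::bayes_factor(pps, 0.3)) > 0))
})

test_that("a prior with no positive mass yields zero Bayes factors", {
  tr <- rel_test_tree(4)
  sim <- simulate_codon_alignment(tr, 40,
                                  data.frame(fraction = 1, dN = 1, dS = 1),
                                  list(R = c(1, 1, 1)), seed = 77)
  freqs <- f3x4_frequencies(sim$alignment)
  model <- structure(list(R = c(AT = 1, CT = 1, GT = 1), scale = 1,
                          ds_values = c(1, 2), ds_weights = c(0.5, 0.5),
                          dn_values = c(0.2, 0.5),
                          dn_weights = c(0.5, 0.5),
                          pos_freqs = freqs$pos_freqs,
                          tree = stats::reorder(tr, "postorder")),
                     class = "rel_model")
  res <- site_bayes_factors(model, sim$alignment)
  expect_true(all(res$BF_positive == 0))
  expect_true(all(res$PP_positive == 0))
  cls <- classify_sites(res)
  expect_false(any(cls$category %in% c("strong_positive", "weak_positive")))
})

test_that("site categories respect the Bayes factor thresholds", {
  res <- data.frame(site = 1:5, ref_pos = c(9, 62, 70, 100, 101),
                    PP_positive = c(0.8, 0.74, 0.38, 0.1, 0.1),
                    BF_positive = c(107, 74, 16, 49.999, 2),
                    BF_negative = c(0, 0, 0, 0, 80))
  class(res) <- c("site_selection_result", class(res))
  cls <- classify_sites(res)
  expect_equal(as.character(cls$category),
               c("strong_positive", "strong_positive", "weak_positive",
                 "weak_positive", "negative"))
  expect_equal(unname(attr(cls, "counts")["strong_positive"]), 2,
               ignore_attr = TRUE)
  expect_error(classify_sites(res, strong = 10, weak_low = 50),
               "thresholds")
})

test_that("planted positive sites rank above neutral sites", {
  tr <- rel_test_tree(6)
  sim <- simulate_codon_alignment(tr, 200,
                                  data.frame(fraction = c(0.9, 0.1),
                                             dN = c(1, 4), dS = c(1, 1)),
                                  list(R = c(1.5, 1.2, 0.9)), seed = 91)
  fit <- fit_rel_model(sim$alignment, tr, n_restarts = 1, max_iter = 2,
                       opt_maxit = 10)
  bf <- site_bayes_factors(fit, sim$alignment)
  planted <- sim$manifest$ground_truth$site_class == 2
  expect_gt(median(bf$PP_positive[planted]),
            median(bf$PP_positive[!planted]))
})
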