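make_records <- function(df) {
  # expand a compact spec (one row per bio rep) into the Ct schema with two
  # identical technical replicates
  rbind(transform(df, tech_rep = 1), transform(df, tech_rep = 2))
}

test_that("primer efficiency follows the dilution-slope formula", {
  perfect <- data.frame(log10_input = 0:-3,
                        ct = 20 + 3.321928 * (0:3))
  pe <- primer_efficiency(perfect)
  expect_equal(pe$factor, 2, tolerance = 1e-5)
  expect_equal(pe$efficiency_percent, 100, tolerance = 1e-3)
  pe2 <- primer_efficiency(data.frame(l = c(0, -1, -2), ct = c(20, 23.6, 27.2)))
  expect_equal(pe2$factor, 10^(1 / 3.6), tolerance = 1e-9)
  expect_error(primer_efficiency(data.frame(l = c(0, -1), ct = c(20, 23))),
               "at least 3")
  bad <- primer_efficiency(data.frame(l = 0:-2, ct = c(22, 21, 20)))
  expect_false(bad$valid)
})

test_that("ddCt arithmetic matches the textbook example", {
  recs <- make_records(data.frame(
    gene = "g", treatment = rep(c("ctrl", "trt"), each = 3),
    bio_rep = rep(1:3, 2),
    ct_target = c(24, 24, 24, 25, 25, 25),
    ct_reference = 20, detectable = TRUE))
  dd <- ddct(recs, "g", "ctrl")
  expect_equal(dd$rel_expr[dd$treatment == "trt"], rep(0.5, 3))
  expect_equal(dd$rel_expr[dd$treatment == "ctrl"], rep(1, 3))
  # treatment identical to control: relative expression one
  recs2 <- recs
  recs2$ct_target[recs2$treatment == "trt"] <- 24
  expect_equal(ddct(recs2, "g", "ctrl")$rel_expr, rep(1, 6))
  expect_error(ddct(recs, "g", "nope"), "control treatment absent")
})

test_that("control geometric mean is exactly one and offsets cancel", {
  sim <- simulate_ct_table("g1", c("ctrl", "up"),
                           matrix(c(1, 3), 1, 2), n_bio_reps = 5,
                           sigma = 0.2, seed = 41)
  dd <- ddct(sim$records, "g1", "ctrl")
  expect_equal(2^(-mean(dd$ddct[dd$treatment == "ctrl"])), 1)
  res <- anova_lsd(dd)
  expect_equal(res$summary$mean_rel_expr[res$summary$treatment == "ctrl"], 1)
  # plate-offset invariance: shifting one replicate's Ct pair changes nothing
  shifted <- sim$records
  pick <- shifted$bio_rep == 2
  shifted$ct_target[pick] <- shifted$ct_target[pick] + 3.7
  shifted$ct_reference[pick] <- shifted$ct_reference[pick] + 3.7
  expect_equal(ddct(shifted, "g1", "ctrl")$rel_expr, dd$rel_expr)
})

test_that("noise-free fold changes are recovered exactly with significance", {
  fc <- matrix(c(1, 4, 0.25), 1, 3,
               dimnames = list("g", c("ctrl", "up", "down")))
  sim <- simulate_ct_table("g", c("ctrl", "up", "down"), fc,
                           n_bio_reps = 4, sigma = 0, seed = 7)
  dd <- ddct(sim$records, "g", "ctrl")
  res <- anova_lsd(dd, min_reps = 3)
  s <- res$summary
  expect_equal(s$mean_rel_expr[match(c("ctrl", "up", "down"), s$treatment)],
               c(1, 4, 0.25))
  expect_equal(length(unique(s$letters)), 3) # all pairwise significant
  # planted pattern at realistic noise
  fc2 <- matrix(c(1, 4, 0.25, 1), 1, 4,
                dimnames = list("g", c("ctrl", "up", "down", "same")))
  sim2 <- simulate_ct_table("g", colnames(fc2), fc2, n_bio_reps = 5,
                            sigma = 0.15, seed = 13)
  res2 <- anova_lsd(ddct(sim2$records, "g", "ctrl"))
  s2 <- res2$summary
  expect_lte(res2$anova_p, 0.05)
  expect_true(s2$letters[s2$treatment == "up"] !=
                s2$letters[s2$treatment == "ctrl"])
  expect_true(s2$letters[s2$treatment == "down"] !=
                s2$letters[s2$treatment == "ctrl"])
  expect_true(grepl(substr(s2$letters[s2$treatment == "ctrl"], 1, 1),
                    s2$letters[s2$treatment == "same"]) ||
                grepl(substr(s2$letters[s2$treatment == "same"], 1, 1),
                      s2$letters[s2$treatment == "ctrl"]))
})

test_that("LSD letters match a hand-computed oracle on a 3x3 table", {
  # three treatments, three replicates each, analyzed on the log2 scale
  y <- list(ctrl = c(0, 0.1, -0.1), mid = c(0.9, 1.0, 1.1),
            far = c(2.4, 2.5, 2.6))
  recs <- make_records(data.frame(
    gene = "g",
    treatment = rep(names(y), each = 3), bio_rep = rep(1:3, 3),
    ct_target = 24 - unlist(y), ct_reference = 20, detectable = TRUE))
  dd <- ddct(recs, "g", "ctrl")
  res <- anova_lsd(dd)
  # oracle: pooled MSE from the three group variances, LSD at alpha 0.05
  means <- vapply(y, mean, numeric(1)) - mean(y$ctrl)
  mse <- mean(vapply(y, var, numeric(1)))
  lsd <- qt(0.975, 6) * sqrt(mse * (2 / 3))
  expect_true(all(abs(diff(sort(means))) > lsd)) # all pairs separate
  expect_equal(length(unique(res$summary$letters)), 3)
  expect_equal(res$mse, mse, tolerance = 1e-9)
  expect_equal(res$df_error, 6)
  # all-identical values collapse to a single letter
  recs0 <- make_records(data.frame(
    gene = "g", treatment = rep(c("a", "b", "c"), each = 3),
    bio_rep = rep(1:3, 3), ct_target = 24, ct_reference = 20,
    detectable = TRUE))
  res0 <- anova_lsd(ddct(recs0, "g", "a"))
  expect_equal(unique(res0$summary$letters), "a")
  # zero within-group variance with distinct means: different letters
  recs1 <- make_records(data.frame(
    gene = "g", treatment = rep(c("a", "b"), each = 3),
    bio_rep = rep(1:3, 2), ct_target = rep(c(24, 25), each = 3),
    ct_reference = 20, detectable = TRUE))
  res1 <- anova_lsd(ddct(recs1, "g", "a"))
  expect_equal(length(unique(res1$summary$letters)), 2)
})

test_that("N/D states propagate and never become zeros", {
  fc <- matrix(c(1, NA, 2), 1, 3,
               dimnames = list("g", c("ctrl", "nd", "up")))
  sim <- simulate_ct_table("g", c("ctrl", "nd", "up"), fc, n_bio_reps = 4,
                           sigma = 0.1, seed = 3)
  dd <- ddct(sim$records, "g", "ctrl")
  expect_true(all(is.na(dd$rel_expr[dd$treatment == "nd"])))
  expect_false(any(dd$rel_expr %in% 0))
  res <- anova_lsd(dd, min_reps = 3)
  expect_equal(res$summary$flag[res$summary$treatment == "nd"], "N/D")
  expect_true(is.na(res$summary$mean_rel_expr[res$summary$treatment ==
                                                "nd"]))
})

test_that("explicit replicate exclusion is honored and bounded", {
  fc <- matrix(c(1, 2), 1, 2, dimnames = list("g", c("ctrl", "trt")))
  sim <- simulate_ct_table("g", c("ctrl", "trt"), fc, n_bio_reps = 5,
                           sigma = 0.1, seed = 23)
  ex <- data.frame(treatment = "trt", bio_rep = 3)
  kept <- exclude_replicates(sim$records, ex)
  expect_equal(sort(unique(kept$bio_rep[kept$treatment == "trt"])),
               c(1, 2, 4, 5))
  expect_equal(nrow(attr(kept, "excluded")), 2) # both technical replicates
  expect_identical(exclude_replicates(sim$records,
                                      data.frame(treatment = character(0),
                                                 bio_rep = integer(0))),
                   sim$records)
  expect_error(exclude_replicates(sim$records,
                                  data.frame(treatment = "trt",
                                             bio_rep = 99)),
               "nonexistent")
  # excluding below the replicate minimum flags the treatment
  ex2 <- data.frame(treatment = "trt", bio_rep = 1:3)
  kept2 <- exclude_replicates(sim$records, ex2)
  res2 <- anova_lsd(ddct(kept2, "g", "ctrl"), min_reps = 3)
  expect_true(res2$skipped)
  expect_equal(res2$summary$flag[res2$summary$treatment == "trt"],
               "insufficient_reps")
})
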