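# RT-qPCR relative expression: primer efficiency from dilution series,
# 2^-ddCt against a reference gene (tubulin), explicit replicate exclusion,
# and per-gene one-way ANOVA with Fisher LSD compact letter groups.

#' Primer amplification efficiency from a dilution series
#'
#' Least-squares slope of Ct against log10 template input; the
#' amplification factor is `10^(-1/slope)` and the efficiency percentage
#' `(factor - 1) * 100` (100% = perfect doubling, slope -3.3219).
#'
#' @param dilution_series data.frame or two-column matrix with `log10_input`
#'   and `ct` (at least 3 points).
#' @return list with `slope`, `factor`, `efficiency_percent`, `valid`
#'   (`FALSE` when the slope is non-negative).
#' @export
primer_efficiency <- function(dilution_series) {
  df <- as.data.frame(dilution_series)
  names(df)[1:2] <- c("log10_input", "ct")
  if (nrow(df) < 3) stop("need at least 3 dilution points")
  slope <- unname(coef(lm(ct ~ log10_input, data = df))[2])
  if (slope >= 0) {
    return(list(slope = slope, factor = NA_real_,
                efficiency_percent = NA_real_, valid = FALSE))
  }
  fac <- 10^(-1 / slope)
  list(slope = slope, factor = fac,
       efficiency_percent = (fac - 1) * 100, valid = TRUE)
}

validate_ct_records <- function(records) {
  need <- c("gene", "treatment", "bio_rep", "tech_rep", "ct_target",
            "ct_reference", "detectable")
  missing <- setdiff(need, names(records))
  if (length(missing)) stop("Ct table missing columns: ",
                            paste(missing, collapse = ", "))
  if (any(records$detectable & !is.na(records$ct_target) &
            records$ct_target <= 0)) {
    stop("detectable Ct values must be positive")
  }
  records
}

# average technical replicates into one Ct per biological replicate
average_tech_reps <- function(records) {
  validate_ct_records(records)
  agg <- aggregate(cbind(ct_target, ct_reference) ~
                     gene + treatment + bio_rep, data = records,
                   FUN = mean, na.action = stats::na.pass)
  det <- aggregate(detectable ~ gene + treatment + bio_rep, data = records,
                   FUN = all)
  merge(agg, det, by = c("gene", "treatment", "bio_rep"))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per biological replicate, `dCt = Ct_target - Ct_reference`; `ddCt`
#' subtracts the mean control dCt, and relative expression is `2^-ddCt`.
#' The control's geometric-mean relative expression is exactly 1 by
#' construction. Non-detectable targets propagate as `N/D`, never as zero.
#'
#' @param records Ct table (`gene`, `treatment`, `bio_rep`, `tech_rep`,
#'   `ct_target`, `ct_reference`, `detectable`); technical replicates are
#'   averaged first.
#' @param gene gene to analyze.
#' @param control_treatment treatment used as the calibrator.
#' @return data.frame with one row per biological replicate: `treatment`,
#'   `bio_rep`, `dct`, `ddct`, `rel_expr`, `detectable`.
#' @export
ddct <- function(records, gene, control_treatment) {
  avg <- average_tech_reps(records)
  g <- avg[avg$gene == gene, , drop = FALSE]
  if (!nrow(g)) stop("no records for gene ", gene)
  if (!control_treatment %in% g$treatment) {
    stop("control treatment absent for gene ", gene)
  }
  if (any(is.na(g$ct_reference) & g$detectable)) {
    stop("missing reference Ct for gene ", gene)
  }
  g$dct <- g$ct_target - g$ct_reference
  ctrl <- g$treatment == control_treatment & g$detectable
  if (!any(ctrl)) stop("control treatment has no detectable replicates")
  base <- mean(g$dct[ctrl])
  g$ddct <- g$dct - base
  g$rel_expr <- 2^(-g$ddct)
  g$rel_expr[!g$detectable] <- NA_real_
  g$ddct[!g$detectable] <- NA_real_
  g[, c("treatment", "bio_rep", "dct", "ddct", "rel_expr", "detectable")]
}

#' One-way ANOVA with Fisher LSD letter groups
#'
#' Statistics run on the log2 scale (ddCt values) for variance homogeneity;
#' reported means are back-transformed geometric means. All pairwise
#' comparisons use the least-significant-difference test with the pooled
#' ANOVA mean square error at the requested level; compact letters are
#' assigned greedily from the highest mean. Treatments with fewer than
#' `min_reps` detectable replicates are excluded and flagged.
#'
#' @param ddct_table output of [ddct()] (one gene).
#' @param alpha significance level (default 0.05, i.e. 95%).
#' @param min_reps minimum biological replicates per treatment (default 3).
#' @return list of class `expression_result`: `summary` (per treatment:
#'   geometric mean relative expression, n, letters, flags), `anova_p`,
#'   `skipped` (`TRUE` when fewer than 2 treatments had enough data).
#' @export
anova_lsd <- function(ddct_table, alpha = 0.05, min_reps = 3) {
  d <- ddct_table[ddct_table$detectable & !is.na(ddct_table$ddct), ,
                  drop = FALSE]
  n_by <- table(d$treatment)
  ok_treat <- names(n_by)[n_by >= min_reps]
  excluded <- setdiff(unique(ddct_table$treatment), ok_treat)
  d <- d[d$treatment %in% ok_treat, , drop = FALSE]
  all_treat <- unique(ddct_table$treatment)
  summ <- data.frame(treatment = all_treat,
                     mean_rel_expr = NA_real_, n = 0L,
                     letters = NA_character_,
                     flag = ifelse(all_treat %in% excluded,
                                   "insufficient_reps", ""))
  for (t in ok_treat) {
    v <- d$ddct[d$treatment == t]
    summ$mean_rel_expr[summ$treatment == t] <- 2^(-mean(v))
    summ$n[summ$treatment == t] <- length(v)
  }
  nd <- vapply(all_treat, function(t) {
    rows <- ddct_table$treatment == t
    all(!ddct_table$detectable[rows])
  }, logical(1))
  summ$flag[nd] <- "N/D"
  if (length(ok_treat) < 2) {
    return(structure(list(summary = summ, anova_p = NA_real_,
                          skipped = TRUE), class = "expression_result"))
  }
  d$treatment <- factor(d$treatment)
  # negative ddCt = higher expression; analyze -ddct (log2 fold change)
  d$y <- -d$ddct
  fit <- aov(y ~ treatment, data = d)
  an <- summary(fit)[[1]]
  p <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][nrow(an)]
  dfe <- an[["Df"]][nrow(an)]
  means <- tapply(d$y, d$treatment, mean)
  ns <- tapply(d$y, d$treatment, length)
  tcrit <- qt(1 - alpha / 2, dfe)
  k <- length(means)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (mse <= 0) {
      sig[i, j] <- means[i] != means[j]
    } else {
      lsd <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      sig[i, j] <- abs(means[i] - means[j]) > lsd
    }
  }
  letters <- lsd_letters(means, sig)
  for (t in names(letters)) {
    summ$letters[summ$treatment == t] <- letters[[t]]
  }
  structure(list(summary = summ, anova_p = p, mse = mse, df_error = dfe,
                 skipped = FALSE), class = "expression_result")
}

# compact letter display: treatments ordered by decreasing mean; each
# maximal run of mutually non-significant treatments gets one letter
lsd_letters <- function(means, sig) {
  ord <- order(-means)
  k <- length(ord)
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k) {
      cand <- ord[i:(j + 1)]
      if (any(sig[cand, cand])) break
      j <- j + 1
    }
    rng <- i:j
    contained <- any(vapply(groups, function(g) all(rng %in% g), logical(1)))
    if (!contained) groups[[length(groups) + 1L]] <- rng
  }
  letts <- rep("", k)
  for (gi in seq_along(groups)) {
    letts[groups[[gi]]] <- paste0(letts[groups[[gi]]], letters[gi])
  }
  setNames(letts[order(ord)], names(means)[ord][order(ord)])
}

#' Remove named biological replicates before analysis
#'
#' Exclusions are explicit (no automatic outlier detection): each row of
#' `exclusion_list` names a treatment and biological replicate, with an
#' optional `gene` (`NA` drops the replicate for every gene).
#'
#' @param records Ct table.
#' @param exclusion_list data.frame with `treatment`, `bio_rep` and
#'   optionally `gene`.
#' @return the records with exclusions removed; the removed rows are
#'   attached as attribute `"excluded"`.
#' @export
exclude_replicates <- function(records, exclusion_list) {
  if (is.null(exclusion_list) || !nrow(exclusion_list)) return(records)
  drop <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(exclusion_list))) {
    ex <- exclusion_list[i, ]
    hit <- records$treatment == ex$treatment & records$bio_rep == ex$bio_rep
    if (!is.null(ex$gene) && !is.na(ex$gene)) hit <- hit & records$gene == ex$gene
    if (!any(hit)) {
      stop("exclusion names a nonexistent replicate: treatment ",
           ex$treatment, ", bio_rep ", ex$bio_rep)
    }
    drop <- drop | hit
  }
  out <- records[!drop, , drop = FALSE]
  attr(out, "excluded") <- records[drop, , drop = FALSE]
  out
}
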