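# Reverse conservation analysis: empirical-Bayes per-column evolutionary
# rates (high scores = poorly conserved), z-normalization, an n = 7 sliding
# window, I = 0.5 peak calling with >50% gap masking, and the two-group
# functional-divergence classifier.

#' Mask columns with too many gaps
#'
#' @param alignment an `aa_alignment`.
#' @param max_gap_fraction columns whose gap fraction exceeds this are
#'   excluded (default 0.5: a column that is gapped in more than half of the
#'   sequences is dropped; exactly half is kept).
#' @return logical vector, `TRUE` for included columns.
#' @export
mask_gappy_columns <- function(alignment, max_gap_fraction = 0.5) {
  if (ncol(alignment) == 0) return(logical(0))
  gapfrac <- colMeans(matrix(alignment %in% GAP_CHARS,
                             nrow(alignment), ncol(alignment)))
  gapfrac <= max_gap_fraction
}

#' Empirical-Bayes per-column rate scores
#'
#' For each alignment column, the posterior mean relative evolutionary rate
#' under a fixed empirical amino-acid model with a discretized-gamma prior
#' over rates:
#' \deqn{S_c = \sum_k r_k P(c \mid r_k) \pi_k \big/ \sum_k P(c \mid r_k) \pi_k}
#' computed by Felsenstein pruning per category. High scores mark poorly
#' conserved columns. Gap and ambiguity characters are treated as missing
#' data.
#'
#' @param alignment an `aa_alignment`.
#' @param tree guide tree (`phylo` with branch lengths) whose tips match the
#'   alignment ids; if `NULL` a neighbor-joining tree from identity-fraction
#'   distances is built.
#' @param model empirical exchangeability matrix name (`"JTT"`).
#' @param n_rate_categories number of discrete gamma categories (default 16).
#' @param alpha gamma shape of the rate prior (default 1).
#' @return numeric vector of raw S scores, one per alignment column.
#' @export
site_rates <- function(alignment, tree = NULL, model = "JTT",
                       n_rate_categories = 16, alpha = 1) {
  if (is.null(tree)) tree <- identity_nj_tree(alignment)
  if (!setequal(tree$tip.label, rownames(alignment))) {
    stop("guide tree tips do not match alignment ids")
  }
  md <- aa_model_data(model)
  q <- make_q_matrix(md$exchangeability, md$pi)
  fac <- pmat_factory(q, md$pi)
  rates <- phangorn::discrete.gamma(alpha, n_rate_categories)
  tr <- stats::reorder(tree, "postorder")
  aln <- alignment[tr$tip.label, , drop = FALSE]
  partials <- lapply(seq_len(nrow(aln)),
                     function(i) tip_partials(aln[i, ], md$states))
  lens <- tr$edge.length
  loglik <- matrix(NA_real_, ncol(alignment), length(rates))
  for (k in seq_along(rates)) {
    pmats <- lapply(lens, function(t) fac(rates[k] * t))
    loglik[, k] <- prune_loglik(tr, partials, pmats, md$pi)
  }
  # posterior mean rate with a uniform category prior
  mx <- apply(loglik, 1, max)
  w <- exp(loglik - mx)
  as.vector((w %*% rates) / rowSums(w))
}

#' Normalize rate scores and apply the sliding-window average
#'
#' Z-normalizes raw S scores over the included columns (population standard
#' deviation, so mean is exactly 0 and sd exactly 1) and computes the
#' W mean: a centered moving average of width `n` taken over included
#' columns in alignment order, truncated symmetrically at the profile edges
#' (the first included column averages included columns 1..4 when `n = 7`).
#'
#' @param raw_s numeric raw scores per alignment column.
#' @param mask logical inclusion mask (e.g. from [mask_gappy_columns()]);
#'   default: all columns included.
#' @param n window width (odd; default 7).
#' @param map optional [map_to_reference()] result attached for
#'   coordinate reporting.
#' @return list of class `conservation_profile`: data.frame `columns`
#'   (`column`, `included`, `raw_s`, `norm_s`, `w_mean`, `ref_pos`), flag
#'   `degenerate` (zero-variance input), and window width `n`.
#' @export
normalize_and_window <- function(raw_s, mask = NULL, n = 7, map = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(raw_s))
  stopifnot(length(mask) == length(raw_s), n %% 2 == 1)
  inc <- which(mask)
  if (!length(inc)) stop("no included columns")
  x <- raw_s[inc]
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  degenerate <- sdev <= 1e-12 * max(1, abs(mu))
  z <- if (degenerate) rep(0, length(x)) else (x - mu) / sdev
  h <- (n - 1) / 2
  m <- length(z)
  w <- vapply(seq_len(m), function(i) {
    mean(z[max(1, i - h):min(m, i + h)])
  }, numeric(1))
  df <- data.frame(column = seq_along(raw_s), included = mask,
                   raw_s = raw_s, norm_s = NA_real_, w_mean = NA_real_,
                   ref_pos = NA_integer_)
  df$norm_s[inc] <- z
  df$w_mean[inc] <- w
  if (!is.null(map)) df$ref_pos <- map$ref_pos[df$column]
  structure(list(columns = df, degenerate = degenerate, n = n,
                 reference_id = attr(map, "reference_id")),
            class = "conservation_profile")
}

#' Call variable regions from a conservation profile
#'
#' Maximal runs of consecutive included columns whose W mean is at least
#' `I`; runs separated by fewer than `min_gap` included columns are merged.
#' Regions are reported in 1-based inclusive reference coordinates when the
#' profile carries a reference map (regions spanning no mapped column get
#' `NA` bounds), labelled with Roman numerals in order.
#'
#' @param profile a `conservation_profile`.
#' @param I intensity threshold on the W mean (default 0.5).
#' @param min_gap runs closer than this many included columns merge.
#' @return data.frame with `label`, `start`, `end` (reference residues),
#'   `start_col`, `end_col` (alignment columns), `peak_w`.
#' @export
call_variable_regions <- function(profile, I = 0.5, min_gap = 3) {
  df <- profile$columns[profile$columns$included, ]
  if (profile$degenerate || !nrow(df)) return(empty_regions())
  hit <- df$w_mean >= I
  if (!any(hit)) return(empty_regions())
  idx <- which(hit)
  breaks <- which(diff(idx) >= min_gap + 1)
  run_id <- cumsum(c(1, as.integer(seq_along(idx)[-1] %in% (breaks + 1))))
  regions <- lapply(split(idx, run_id), function(ii) {
    span <- min(ii):max(ii) # merged span, including sub-threshold gaps
    rows <- df[span, ]
    data.frame(start = suppressWarnings(min(rows$ref_pos, na.rm = TRUE)),
               end = suppressWarnings(max(rows$ref_pos, na.rm = TRUE)),
               start_col = min(rows$column), end_col = max(rows$column),
               peak_w = max(rows$w_mean, na.rm = TRUE))
  })
  out <- do.call(rbind, regions)
  out$start[!is.finite(out$start)] <- NA_integer_
  out$end[!is.finite(out$end)] <- NA_integer_
  out <- out[order(out$start_col), , drop = FALSE]
  out <- cbind(label = as.character(as.roman(seq_len(nrow(out)))), out)
  rownames(out) <- NULL
  out
}

empty_regions <- function() {
  data.frame(label = character(0), start = integer(0), end = integer(0),
             start_col = integer(0), end_col = integer(0),
             peak_w = numeric(0))
}

#' Classify regions as functionally divergent between two paralog groups
#'
#' Each group is profiled on its own alignment; profiles are compared
#' through the shared reference sequence's residue coordinates. Every
#' variable region found in either group is classified by the two-group
#' intensity rule on the region-mean W: high variation (`>= I`) in one group
#' combined with low variation (`< I`) in the other marks functional
#' divergence.
#'
#' @param profile_a,profile_b `conservation_profile`s carrying reference
#'   maps onto the same reference sequence.
#' @param I intensity threshold (default 0.5).
#' @param min_gap passed to [call_variable_regions()].
#' @return data.frame with `label`, `start`, `end` (reference residues),
#'   `mean_w_a`, `mean_w_b` and
#'   `class` in `divergent-in-A`, `divergent-in-B`, `variable-in-both`,
#'   `conserved-in-both`.
#' @export
call_divergent_regions <- function(profile_a, profile_b, I = 0.5,
                                   min_gap = 3) {
  wa <- ref_w_vector(profile_a)
  wb <- ref_w_vector(profile_b)
  shared <- intersect(names(wa), names(wb))
  if (!length(shared)) stop("profiles have disjoint reference coverage")
  ra <- call_variable_regions(profile_a, I = I, min_gap = min_gap)
  rb <- call_variable_regions(profile_b, I = I, min_gap = min_gap)
  regions <- rbind(ra[, c("start", "end")], rb[, c("start", "end")])
  regions <- regions[!is.na(regions$start), , drop = FALSE]
  if (!nrow(regions)) {
    return(data.frame(label = character(0), start = integer(0),
                      end = integer(0), mean_w_a = numeric(0),
                      mean_w_b = numeric(0), class = character(0)))
  }
  regions <- merge_intervals(regions[order(regions$start), , drop = FALSE])
  mean_over <- function(w, lo, hi) {
    pos <- as.integer(names(w))
    v <- w[pos >= lo & pos <= hi]
    if (!length(v)) NA_real_ else mean(v)
  }
  regions$mean_w_a <- mapply(function(s, e) mean_over(wa, s, e),
                             regions$start, regions$end)
  regions$mean_w_b <- mapply(function(s, e) mean_over(wb, s, e),
                             regions$start, regions$end)
  a_hi <- !is.na(regions$mean_w_a) & regions$mean_w_a >= I
  b_hi <- !is.na(regions$mean_w_b) & regions$mean_w_b >= I
  regions$class <- ifelse(a_hi & !b_hi, "divergent-in-A",
                    ifelse(b_hi & !a_hi, "divergent-in-B",
                     ifelse(a_hi & b_hi, "variable-in-both",
                            "conserved-in-both")))
  cbind(label = as.character(as.roman(seq_len(nrow(regions)))), regions)
}

ref_w_vector <- function(profile) {
  df <- profile$columns
  ok <- df$included & !is.na(df$ref_pos) & !is.na(df$w_mean)
  setNames(df$w_mean[ok], df$ref_pos[ok])
}

merge_intervals <- function(df) {
  out <- df[1, , drop = FALSE]
  if (nrow(df) > 1) for (i in 2:nrow(df)) {
    last <- nrow(out)
    if (df$start[i] <= out$end[last] + 1) {
      out$end[last] <- max(out$end[last], df$end[i])
    } else {
      out <- rbind(out, df[i, ])
    }
  }
  rownames(out) <- NULL
  out
}
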