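# Random-effects-likelihood (REL) site-selection scan: a codon model whose
# synonymous and nonsynonymous rates at each site are drawn from discrete
# class distributions (K_s x K_n independent grid), fitted by maximum
# likelihood with empirical-Bayes per-site posteriors and Bayes factors for
# positive selection.

rel_cells <- function(ds_values, dn_values) {
  expand.grid(ds = ds_values, dn = dn_values, KEEP.OUT.ATTRS = FALSE)
}

rel_cell_weights <- function(ds_weights, dn_weights) {
  as.vector(outer(ds_weights, dn_weights))
}

# pattern x cell log-likelihood matrix for one parameter set
rel_site_cell_loglik <- function(tree, partials, structure, cells, scale) {
  lens <- stats::reorder(tree, "postorder")$edge.length * scale
  out <- matrix(NA_real_, nrow(partials[[1]]), nrow(cells))
  for (g in seq_len(nrow(cells))) {
    q <- mg94_q(structure, cells$ds[g], cells$dn[g])
    fac <- pmat_factory(q, structure$pi_codon)
    pmats <- lapply(lens, fac)
    out[, g] <- prune_loglik(tree, partials, pmats, structure$pi_codon)
  }
  out
}

rel_loglik_from_cells <- function(cell_ll, w_cells, pattern_weights) {
  mx <- apply(cell_ll, 1, max)
  sum(pattern_weights * (mx + log(as.vector(exp(cell_ll - mx) %*% w_cells))))
}

#' Fit the REL codon selection model
#'
#' Maximizes the random-effects likelihood
#' \eqn{\sum_s \log \sum_g w_g P(\mathrm{site}_s \mid g, \theta)} over the
#' nucleotide exchangeabilities (R_AT, R_CT, R_GT; A-C, A-G, C-G fixed at
#' 1), a branch-length scale on the fixed input topology, and the dS/dN
#' class values and weights of the `K_s x K_n` grid, by alternating an EM
#' update of the weights with bounded numerical optimization of the
#' continuous parameters. The log-likelihood is non-decreasing across
#' iterations; convergence is declared when it improves by less than `tol`.
#' Codon frequencies are F3x4 from the alignment; dS class values are
#' renormalized to mean 1 (absorbed into the branch scale) for
#' identifiability.
#'
#' @param codon_alignment an in-frame `codon_alignment` (at least 3
#'   sequences).
#' @param tree `phylo` with branch lengths, tips matching the alignment.
#' @param K_s,K_n number of dS and dN classes (default 3 each).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum outer iterations.
#' @param n_restarts number of jittered restarts (default 3; the best
#'   likelihood wins).
#' @param seed seed controlling restart jitter.
#' @param opt_maxit per-block iteration cap for the numerical optimizer.
#' @return list of class `rel_model` with elements `R` (named AT/CT/GT),
#'   `scale`, `ds_values`, `ds_weights`, `dn_values`, `dn_weights`,
#'   `pos_freqs`, `logLik`, `trace`, `converged`, `tree`.
#' @export
fit_rel_model <- function(codon_alignment, tree, K_s = 3, K_n = 3,
                          tol = 1e-6, max_iter = 30, n_restarts = 3,
                          seed = 1, opt_maxit = 20) {
  if (nrow(codon_alignment) < 3) stop("need at least 3 sequences")
  if (!setequal(tree$tip.label, rownames(codon_alignment))) {
    stop("tree tips do not match alignment ids")
  }
  check_stop_codons(codon_alignment)
  idx <- codon_index_matrix(codon_alignment)
  freqs <- f3x4_frequencies(codon_alignment)
  tr <- stats::reorder(tree, "postorder")
  if (is.null(tr$edge.length)) stop("tree needs branch lengths")
  idx <- idx[, tr$tip.label, drop = FALSE]
  # pattern compression
  key <- apply(idx, 1, paste, collapse = ",")
  upat <- !duplicated(key)
  pat_of_site <- match(key, key[upat])
  pidx <- idx[upat, , drop = FALSE]
  pw <- as.vector(table(factor(pat_of_site, levels = seq_len(sum(upat)))))
  ncod <- length(sense_codons())
  partials <- lapply(seq_len(ncol(pidx)), function(i) {
    m <- matrix(0, nrow(pidx), ncod)
    known <- !is.na(pidx[, i])
    m[cbind(which(known), pidx[known, i])] <- 1
    m[!known, ] <- 1
    m
  })

  run_one <- function(jitter_seed, jitter) {
    init <- list(R = c(1, 1, 1), scale = 1,
                 ds = seq(0.5, 2, length.out = K_s),
                 dn = seq(0.25, 2.5, length.out = K_n),
                 ws = rep(1 / K_s, K_s), wn = rep(1 / K_n, K_n))
    if (jitter) {
      local_seed(jitter_seed, {
        init$R <- init$R * exp(rnorm(3, 0, 0.3))
        init$ds <- sort(init$ds * exp(rnorm(K_s, 0, 0.3)))
        init$dn <- sort(init$dn * exp(rnorm(K_n, 0, 0.3)))
        init$scale <- init$scale * exp(rnorm(1, 0, 0.3))
      })
    }
    rel_fit_inner(init, tr, partials, pw, freqs, tol, max_iter, opt_maxit)
  }

  best <- run_one(NA, FALSE)
  if (n_restarts > 1) for (r in seq_len(n_restarts - 1)) {
    cand <- run_one(derive_seed(seed, r), TRUE)
    if (cand$logLik > best$logLik) best <- cand
  }
  best$pos_freqs <- freqs$pos_freqs
  best$tree <- tr
  best$K_s <- K_s; best$K_n <- K_n
  class(best) <- "rel_model"
  best
}

rel_fit_inner <- function(par, tree, partials, pw, freqs, tol, max_iter,
                          opt_maxit) {
  ll_of <- function(p) {
    st <- mg94_structure(p$R, freqs$pos_freqs)
    cells <- rel_cells(p$ds, p$dn)
    cl <- rel_site_cell_loglik(tree, partials, st, cells, p$scale)
    list(cell_ll = cl,
         logLik = rel_loglik_from_cells(cl, rel_cell_weights(p$ws, p$wn), pw))
  }
  cur <- ll_of(par)
  trace <- cur$logLik
  converged <- FALSE
  K_s <- length(par$ds); K_n <- length(par$dn)
  for (it in seq_len(max_iter)) {
    ll_prev <- cur$logLik
    # --- EM update of the product weights (monotone in the likelihood)
    for (em in 1:5) {
      w <- rel_cell_weights(par$ws, par$wn)
      mx <- apply(cur$cell_ll, 1, max)
      lik <- exp(cur$cell_ll - mx)
      resp <- lik * rep(w, each = nrow(lik))
      resp <- resp / rowSums(resp)
      tot <- colSums(resp * pw) / sum(pw)
      m <- matrix(tot, K_s, K_n)
      par$ws <- rowSums(m); par$wn <- colSums(m)
      par$ws <- par$ws / sum(par$ws); par$wn <- par$wn / sum(par$wn)
    }
    ll_current <- rel_loglik_from_cells(cur$cell_ll,
                                        rel_cell_weights(par$ws, par$wn), pw)
    # --- numerical blocks: (scale, R), then class values; each block
    # starts at the current point, so optim can only improve it
    obj_sr <- function(x) {
      p2 <- par; p2$scale <- exp(x[1]); p2$R <- exp(x[2:4])
      -ll_of(p2)$logLik
    }
    o1 <- optim(log(c(par$scale, par$R)), obj_sr, method = "Nelder-Mead",
                control = list(maxit = opt_maxit))
    if (-o1$value > ll_current) {
      par$scale <- exp(o1$par[1]); par$R <- exp(o1$par[2:4])
      ll_current <- -o1$value
    }
    obj_vals <- function(x) {
      p2 <- par
      p2$ds <- exp(x[seq_len(K_s)]); p2$dn <- exp(x[K_s + seq_len(K_n)])
      -ll_of(p2)$logLik
    }
    o2 <- optim(log(c(par$ds, par$dn)), obj_vals, method = "Nelder-Mead",
                control = list(maxit = opt_maxit))
    if (-o2$value > ll_current) {
      par$ds <- exp(o2$par[seq_len(K_s)])
      par$dn <- exp(o2$par[K_s + seq_len(K_n)])
      ll_current <- -o2$value
    }
    # identifiability: mean dS = 1, absorbed into the branch scale
    m <- sum(par$ws * par$ds)
    par$ds <- par$ds / m; par$dn <- par$dn / m; par$scale <- par$scale * m
    cur <- ll_of(par)
    if (cur$logLik < ll_prev - 1e-6) {
      # numerical safety: never accept a worse state
      stop("internal error: log-likelihood decreased during REL fit")
    }
    trace <- c(trace, cur$logLik)
    if (cur$logLik - ll_prev < tol) { converged <- TRUE; break }
  }
  list(R = setNames(par$R, c("AT", "CT", "GT")), scale = par$scale,
       ds_values = par$ds, ds_weights = par$ws,
       dn_values = par$dn, dn_weights = par$wn,
       logLik = cur$logLik, trace = trace, converged = converged)
}

#' Per-site posterior selection probabilities and Bayes factors
#'
#' Empirical-Bayes posterior over the fitted dS/dN grid at every codon
#' site. The posterior probability of positive selection is the posterior
#' mass on cells with dN > dS; the Bayes factor is the ratio of posterior
#' to prior odds of that event (0 when the prior positive mass is 0,
#' `Inf` when the posterior is 1 with prior mass below 1). A symmetric
#' Bayes factor for dN < dS supports negative-selection calls.
#'
#' @param model a fitted [fit_rel_model()].
#' @param codon_alignment the codon alignment to score (typically the one
#'   the model was fitted to).
#' @param map optional [map_to_reference()] built on the matching protein
#'   alignment, used to report reference residue positions.
#' @return data.frame of class `site_selection_result`: `site`, `ref_pos`,
#'   `PP_positive`, `BF_positive`, `BF_negative`.
#' @export
site_bayes_factors <- function(model, codon_alignment, map = NULL) {
  if (!inherits(model, "rel_model")) stop("model must be a fitted rel_model")
  idx <- codon_index_matrix(codon_alignment)
  tr <- model$tree
  idx <- idx[, tr$tip.label, drop = FALSE]
  ncod <- length(sense_codons())
  partials <- lapply(seq_len(ncol(idx)), function(i) {
    m <- matrix(0, nrow(idx), ncod)
    known <- !is.na(idx[, i])
    m[cbind(which(known), idx[known, i])] <- 1
    m[!known, ] <- 1
    m
  })
  st <- mg94_structure(model$R, model$pos_freqs)
  cells <- rel_cells(model$ds_values, model$dn_values)
  cl <- rel_site_cell_loglik(tr, partials, st, cells, model$scale)
  w <- rel_cell_weights(model$ds_weights, model$dn_weights)
  pos_cells <- cells$dn > cells$ds
  neg_cells <- cells$dn < cells$ds
  mx <- apply(cl, 1, max)
  lik <- exp(cl - mx)
  post <- lik * rep(w, each = nrow(lik))
  post <- post / rowSums(post)
  pp_pos <- as.vector(post %*% pos_cells)
  pp_neg <- as.vector(post %*% neg_cells)
  pi_pos <- sum(w[pos_cells])
  pi_neg <- sum(w[neg_cells])
  out <- data.frame(site = seq_len(nrow(cl)),
                    ref_pos = NA_integer_,
                    PP_positive = pp_pos,
                    BF_positive = bayes_factor(pp_pos, pi_pos),
                    BF_negative = bayes_factor(pp_neg, pi_neg))
  if (!is.null(map)) {
    # codon site s corresponds to column s of the companion protein
    # alignment the map was built on
    ok <- out$site <= nrow(map)
    out$ref_pos[ok] <- map$ref_pos[out$site[ok]]
  }
  class(out) <- c("site_selection_result", class(out))
  out
}

bayes_factor <- function(pp, prior) {
  if (prior <= 0) return(rep(0, length(pp)))
  if (prior >= 1) return(rep(1, length(pp)))
  prior_odds <- prior / (1 - prior)
  ifelse(pp >= 1, Inf, (pp / (1 - pp)) / prior_odds)
}

#' Classify codon sites by selection category
#'
#' `strong_positive` for positive Bayes factor at least `strong` (default
#' 50), `weak_positive` for at least `weak_low` (default 10) but below
#' `strong`, `negative` for a negative-direction Bayes factor at least
#' `strong` in a site not called positive, `neutral` otherwise.
#'
#' @param result a `site_selection_result`.
#' @param strong,weak_low,weak_high Bayes factor thresholds (the weak band
#'   is `[weak_low, strong)`; `weak_high` documents its printed upper edge
#'   and must stay below `strong`).
#' @return the input with a `category` column, plus a `counts` attribute.
#' @export
classify_sites <- function(result, strong = 50, weak_low = 10,
                           weak_high = 49) {
  if (!(weak_low <= weak_high && weak_high < strong)) {
    stop("thresholds must satisfy weak_low <= weak_high < strong")
  }
  bfp <- result$BF_positive
  bfn <- result$BF_negative
  cat <- ifelse(bfp >= strong, "strong_positive",
          ifelse(bfp >= weak_low, "weak_positive",
           ifelse(bfn >= strong, "negative", "neutral")))
  result$category <- factor(cat, levels = c("strong_positive",
                                            "weak_positive", "negative",
                                            "neutral"))
  attr(result, "counts") <- table(result$category)
  result
}
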