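#' Single-rate linear birth--death transition probability
#'
#' Probability that a gene family of size `s` at the top of a branch of
#' duration `t` (Myr) has size `c` at the bottom, under the linear
#' birth--death process in which every gene copy is independently gained or
#' lost at the same rate `lambda` (per gene per Myr). Uses the classical
#' closed form for the equal-rates process with
#' `alpha = lambda*t / (1 + lambda*t)`:
#' \deqn{P(c\,|\,s) = \sum_{k=0}^{\min(s,c)} \binom{s}{k}
#'   \binom{s+c-k-1}{s-1} \alpha^{s+c-2k} (1-2\alpha)^k}
#' with size 0 absorbing.
#'
#' @param s parent (ancestral) count, non-negative integer scalar.
#' @param c child (descendant) count, non-negative integer (vectorized).
#' @param lambda gain/loss rate per gene per Myr, `>= 0`.
#' @param t branch duration in Myr, `>= 0`.
#' @return numeric vector of probabilities, one per element of `c`.
#' @export
bd_transition_prob <- function(s, c, lambda, t) {
  if (length(s) != 1L || s < 0 || s != round(s)) {
    stop("s must be a single non-negative integer")
  }
  if (any(c < 0) || any(c != round(c))) stop("c must be non-negative integers")
  if (lambda < 0 || t < 0) stop("lambda and t must be non-negative")
  alpha <- lambda * t / (1 + lambda * t)
  if (alpha == 0) return(as.numeric(c == s))
  if (s == 0) return(as.numeric(c == 0))
  if (lambda * t <= 1) {
    return(vapply(c, function(ci) bd_prob_one(s, ci, alpha), numeric(1)))
  }
  # the closed form alternates in sign once lambda*t > 1 and cancels
  # catastrophically for large s+c; go through the stable matrix route
  # (cap rounded up so the cached eigendecompositions get reused)
  cap <- 50L * as.integer(ceiling((2 * (s + max(c)) + 20) / 50))
  M <- bd_transition_matrix(lambda, t, cap)
  M[s + 1L, c + 1L]
}

bd_prob_one <- function(s, c, alpha) {
  # valid for alpha <= 1/2 (lambda*t <= 1): every term is non-negative
  k <- 0:min(s, c)
  la <- log(alpha)
  one_m2a <- 1 - 2 * alpha
  mag <- exp(lchoose(s, k) + lchoose(s + c - k - 1, s - 1) +
               (s + c - 2 * k) * la + k * log(abs(one_m2a) + (one_m2a == 0)))
  mag[k > 0 & one_m2a == 0] <- 0
  min(max(sum(mag), 0), 1)
}

#' Birth--death transition matrix over truncated family sizes
#'
#' @param lambda rate per gene per Myr.
#' @param t branch duration, Myr.
#' @param cap truncation cap; states are 0..cap.
#' @param headroom extra states carried above the cap so that within-branch
#'   excursions beyond it do not bias the returned block (the deficit of
#'   the returned rows is then only the genuine end-state truncation).
#' @return a `(cap+1) x (cap+1)` matrix `P[s+1, c+1] = P(c | s)`.
#' @export
bd_transition_matrix <- function(lambda, t, cap, headroom = 60L) {
  alpha <- lambda * t / (1 + lambda * t)
  P <- matrix(0, cap + 1, cap + 1)
  if (alpha == 0) {
    diag(P) <- 1
    return(P)
  }
  # transitions into extinction have the exact closed form alpha^s; the
  # sub-chain on 1..cap+headroom is similar to a symmetric tridiagonal
  # matrix (diagonal scaling by 1/sqrt(n)), whose eigendecomposition
  # depends only on its size — cached, so each (lambda, t) costs two dense
  # products
  work <- cap + headroom
  eig <- bd_subchain_eigen(work)
  inner <- eig$left %*% (exp(lambda * t * eig$values) * eig$right)
  P[1, 1] <- 1
  P[-1, 1] <- alpha^(1:cap)
  P[-1, -1] <- inner[1:cap, 1:cap]
  pmin(pmax(P, 0), 1)
}

bd_eigen_cache <- new.env(parent = emptyenv())

bd_subchain_eigen <- function(cap) {
  key <- as.character(cap)
  if (!is.null(bd_eigen_cache[[key]])) return(bd_eigen_cache[[key]])
  n <- 1:cap
  S <- matrix(0, cap, cap)
  if (cap > 1) {
    off <- sqrt(n[-cap] * (n[-cap] + 1))
    S[cbind(1:(cap - 1), 2:cap)] <- off
    S[cbind(2:cap, 1:(cap - 1))] <- off
  }
  diag(S) <- -2 * n
  e <- eigen(S, symmetric = TRUE)
  d <- 1 / sqrt(n) # T = D^-1 S D with D = diag(d)
  res <- list(values = e$values,
              left = (1 / d) * e$vectors,
              right = t(e$vectors) * rep(d, each = cap))
  bd_eigen_cache[[key]] <- res
  res
}

#' Birth--death model specification
#'
#' @param lambda_rate gain/loss rate per gene per Myr.
#' @param count_cap family-size truncation cap (default rule:
#'   `2 * max observed + 10`, applied by the fitting functions).
#' @param logLik achieved log-likelihood (filled by [estimate_lambda()]).
#' @param boundary_warning `TRUE` when the estimate sits on the `lambda = 0`
#'   boundary (no family-size change observed).
#' @return list of class `bd_model`.
#' @export
bd_model <- function(lambda_rate, count_cap, logLik = NA_real_,
                     boundary_warning = FALSE) {
  stopifnot(lambda_rate >= 0, count_cap >= 1)
  structure(list(lambda_rate = lambda_rate, count_cap = as.integer(count_cap),
                 logLik = logLik, boundary_warning = boundary_warning),
            class = "bd_model")
}

default_cap <- function(max_count) as.integer(2L * max(1L, max_count) + 10L)

#' Uniform non-extinct root-size prior
#'
#' Probability vector over family sizes 0..cap that is uniform on 1..cap:
#' the default root prior of the birth--death analyses (a root size of 0
#' is excluded, since observed families existed at the root).
#'
#' @param cap truncation cap.
#' @return numeric vector of length `cap + 1`.
#' @export
uniform_root_prior <- function(cap) {
  c(0, rep(1 / cap, cap))
}

# Per-edge transition matrices in the tree's edge order.
edge_transition_matrices <- function(tree, lambda, cap) {
  lens <- tree$edge.length
  mats <- vector("list", length(lens))
  # identical branch lengths share one matrix
  key <- match(lens, unique(lens))
  uniq <- lapply(unique(lens), function(t) bd_transition_matrix(lambda, t, cap))
  for (i in seq_along(lens)) mats[[i]] <- uniq[[key[i]]]
  mats
}

# Vectorized pruning log-likelihood for many families at once.
# counts: families x tips matrix with colnames matching tree tip labels.
bd_family_loglik <- function(tree, counts, lambda, cap = NULL,
                             root_prior = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  missing <- setdiff(tree$tip.label, colnames(counts))
  if (length(missing)) stop("tips missing counts: ",
                            paste(missing, collapse = ", "))
  counts <- counts[, tree$tip.label, drop = FALSE]
  if (is.null(cap)) cap <- default_cap(max(counts))
  if (max(counts) > cap) stop("observed count exceeds count_cap")
  if (is.null(root_prior)) root_prior <- uniform_root_prior(cap)
  stopifnot(length(root_prior) == cap + 1)

  tr <- stats::reorder(tree, "postorder") # ape reorder method
  nf <- nrow(counts)
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  mats <- edge_transition_matrices(tr, lambda, cap)

  partial <- vector("list", nnode)
  logscale <- matrix(0, nf, nnode)
  for (i in seq_len(ntip)) {
    m <- matrix(0, nf, cap + 1)
    m[cbind(seq_len(nf), counts[, i] + 1L)] <- 1
    partial[[i]] <- m
  }
  parents <- tr$edge[, 1]
  children <- tr$edge[, 2]
  for (e in seq_along(parents)) {
    p <- parents[e]; ch <- children[e]
    msg <- partial[[ch]] %*% t(mats[[e]]) # families x parent-states
    if (is.null(partial[[p]])) {
      partial[[p]] <- msg
      logscale[, p] <- logscale[, ch]
    } else {
      partial[[p]] <- partial[[p]] * msg
      logscale[, p] <- logscale[, p] + logscale[, ch]
    }
    mx <- apply(partial[[p]], 1, max)
    mx[mx == 0] <- 1
    partial[[p]] <- partial[[p]] / mx
    logscale[, p] <- logscale[, p] + log(mx)
  }
  root <- ntip + 1L
  lik <- as.vector(partial[[root]] %*% root_prior)
  log(lik) + logscale[, root]
}

#' Log-likelihood of one family's tip counts under a birth--death model
#'
#' Felsenstein pruning over the truncated transition kernel, marginalizing
#' all internal family sizes, with the root size drawn from `root_prior`
#' (default: uniform over 1..cap, i.e. conditioned on a non-extinct root).
#'
#' @param tree calibrated `dated_species_tree`.
#' @param counts named integer vector of tip counts (names = tip labels).
#' @param model a [bd_model()].
#' @param root_prior optional probability vector over sizes 0..cap.
#' @return log-likelihood (scalar; `-Inf` for impossible data).
#' @export
family_log_likelihood <- function(tree, counts, model, root_prior = NULL) {
  bd_family_loglik(tree, counts, model$lambda_rate, cap = model$count_cap,
                   root_prior = root_prior)
}

#' Filter families for birth--death analysis
#'
#' Retains families with at least 2 genes in at least one species and a
#' nonzero count in at least 2 species; order is preserved.
#'
#' @param table a `family_count_table`.
#' @return the filtered table.
#' @export
filter_families <- function(table) {
  m <- count_matrix(table)
  keep <- apply(m, 1, max) >= 2 & rowSums(m > 0) >= 2
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the birth--death rate from a family count table
#'
#' Maximizes the summed per-family pruning log-likelihood over a single
#' gain/loss rate by bounded one-dimensional optimization.
#'
#' @param table a (filtered) `family_count_table`.
#' @param tree calibrated `dated_species_tree` whose tips match the table's
#'   species columns.
#' @param cap truncation cap (default `2 * max observed + 10`).
#' @param upper upper bound for the rate search (per gene per Myr).
#' @param root_prior optional root-size prior.
#' @return a [bd_model()] with the fitted `lambda_rate` and log-likelihood;
#'   `boundary_warning` is set when no family varies across species.
#' @export
estimate_lambda <- function(table, tree, cap = NULL, upper = 1,
                            root_prior = NULL) {
  m <- count_matrix(table, species = tree$tip.label)
  if (is.null(cap)) cap <- default_cap(max(m))
  constant <- apply(m, 1, function(x) all(x == x[1]))
  if (all(constant)) {
    ll <- sum(bd_family_loglik(tree, m, 0, cap = cap, root_prior = root_prior))
    return(bd_model(0, cap, logLik = ll, boundary_warning = TRUE))
  }
  nll <- function(lam) -sum(bd_family_loglik(tree, m, lam, cap = cap,
                                             root_prior = root_prior))
  opt <- optimize(nll, interval = c(1e-8, upper), tol = 1e-8)
  bd_model(opt$minimum, cap, logLik = -opt$objective,
           boundary_warning = opt$minimum <= 2e-8)
}

# Sample tip counts for n families from the model by drawing the root size
# from the prior and each child size from the branch kernel (exact).
sample_family_counts <- function(tree, lambda, n, cap, root_prior) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  mats <- edge_transition_matrices(tr, lambda, cap)
  states <- matrix(NA_integer_, n, nnode)
  root <- ntip + 1L
  states[, root] <- sample.int(cap + 1L, n, replace = TRUE,
                               prob = root_prior) - 1L
  # preorder = reversed postorder edge sequence
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sp <- states[, p]
    out <- integer(n)
    for (s in unique(sp)) {
      idx <- which(sp == s)
      out[idx] <- sample.int(cap + 1L, length(idx), replace = TRUE,
                             prob = mats[[e]][s + 1L, ]) - 1L
    }
    states[, ch] <- out
  }
  tips <- states[, seq_len(ntip), drop = FALSE]
  colnames(tips) <- tr$tip.label
  tips
}

#' Monte Carlo family p-value under the fitted birth--death model
#'
#' Simulates `n_null` families from the model (root size from the prior,
#' then exact branch transitions) and reports the fraction whose pruning
#' log-likelihood is at most the observed family's, with a +1 pseudo-count
#' on numerator and denominator so that p is always in (0, 1].
#'
#' @param counts named tip-count vector for the family under test.
#' @param model fitted [bd_model()].
#' @param tree calibrated species tree.
#' @param n_null number of null simulations (>= 100).
#' @param seed integer seed.
#' @param root_prior optional root-size prior.
#' @return p-value in (0, 1].
#' @export
family_p_value <- function(counts, model, tree, n_null = 1000, seed = 1,
                           root_prior = NULL) {
  tab <- matrix(counts, nrow = 1, dimnames = list(NULL, names(counts)))
  family_p_values(tab, model, tree, n_null = n_null, seed = seed,
                  root_prior = root_prior)
}

#' @rdname family_p_value
#' @param counts_matrix families x species matrix (batch form; the null
#'   log-likelihood sample depends only on the model and is shared).
#' @export
family_p_values <- function(counts_matrix, model, tree, n_null = 1000,
                            seed = 1, root_prior = NULL) {
  if (n_null < 100) stop("n_null must be at least 100")
  if (is.data.frame(counts_matrix)) {
    counts_matrix <- count_matrix(counts_matrix, species = tree$tip.label)
  }
  cap <- model$count_cap
  if (is.null(root_prior)) root_prior <- uniform_root_prior(cap)
  null_tips <- local_seed(seed,
    sample_family_counts(tree, model$lambda_rate, n_null, cap, root_prior))
  ll_null <- bd_family_loglik(tree, null_tips, model$lambda_rate, cap = cap,
                              root_prior = root_prior)
  ll_obs <- bd_family_loglik(tree, counts_matrix, model$lambda_rate,
                             cap = cap, root_prior = root_prior)
  p <- vapply(ll_obs, function(l) (1 + sum(ll_null <= l)) / (n_null + 1),
              numeric(1))
  if (length(p) == 1L) p[[1]] else p
}
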