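# Amino-acid substitution machinery shared by the conservation profiler and
# the alignment simulator: JTT-class empirical exchangeabilities (taken from
# phangorn's model data), discretized-gamma rate categories, eigendecomposed
# transition matrices, and a vectorized Felsenstein pruning engine that works
# for any state space (amino acids here, codons in the selection module).

aa_model_data <- function(model = "JTT") {
  obj <- get(paste0(".", model), envir = asNamespace("phangorn"))
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- obj$Q
  s <- s + t(s)
  pi <- unname(obj$bf)
  states <- toupper(names(obj$bf))
  list(exchangeability = s, pi = pi, states = states)
}

# reversible rate matrix from exchangeabilities and frequencies,
# normalized to one expected substitution per unit time
make_q_matrix <- function(exch, pi) {
  q <- exch %*% diag(pi)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  rate <- -sum(pi * diag(q))
  q / rate
}

# symmetric eigendecomposition of a reversible Q; returns a closure P(t)
pmat_factory <- function(q, pi) {
  d <- sqrt(pi)
  a <- diag(d) %*% q %*% diag(1 / d)
  a <- (a + t(a)) / 2
  eig <- eigen(a, symmetric = TRUE)
  left <- diag(1 / d) %*% eig$vectors
  right <- t(eig$vectors) %*% diag(d)
  vals <- eig$values
  function(t) {
    p <- left %*% (exp(vals * t) * right)
    p[p < 0] <- 0
    p
  }
}

# tip partial likelihood matrices: sites x states indicator, all-ones rows
# for gaps/ambiguity (missing data)
tip_partials <- function(column_chars, states) {
  n <- length(column_chars)
  m <- matrix(0, n, length(states))
  ix <- match(column_chars, states)
  known <- !is.na(ix)
  m[cbind(which(known), ix[known])] <- 1
  m[!known, ] <- 1
  m
}

# vectorized pruning: per-site log-likelihood under per-edge P matrices.
# `partials` is a list over tip indices of (sites x states) matrices.
prune_loglik <- function(tree, partials, pmats, root_freq) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  nsite <- nrow(partials[[1]])
  part <- vector("list", nnode)
  logscale <- matrix(0, nsite, nnode)
  for (i in seq_len(ntip)) part[[i]] <- partials[[i]]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    msg <- part[[ch]] %*% t(pmats[[e]])
    if (is.null(part[[p]])) {
      part[[p]] <- msg
      logscale[, p] <- logscale[, ch]
    } else {
      part[[p]] <- part[[p]] * msg
      logscale[, p] <- logscale[, p] + logscale[, ch]
    }
    mx <- apply(part[[p]], 1, max)
    mx[mx == 0] <- 1
    part[[p]] <- part[[p]] / mx
    logscale[, p] <- logscale[, p] + log(mx)
  }
  root <- ntip + 1L
  log(as.vector(part[[root]] %*% root_freq)) + logscale[, root]
}

# order edge lengths to match reorder(tree, "postorder")
postorder_edge_lengths <- function(tree) {
  stats::reorder(tree, "postorder")$edge.length
}

# neighbor-joining guide tree from identity-fraction distances, used when
# the caller supplies no tree (declared plumbing, not an inference claim)
identity_nj_tree <- function(alignment) {
  n <- nrow(alignment)
  if (n < 3) stop("need at least 3 sequences to build a guide tree")
  d <- matrix(0, n, n, dimnames = list(rownames(alignment),
                                       rownames(alignment)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- alignment[i, ]; b <- alignment[j, ]
    ok <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
    p <- if (any(ok)) mean(a[ok] != b[ok]) else 0
    d[i, j] <- d[j, i] <- p
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  tr
}
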