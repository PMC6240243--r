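# shared fixtures and independent oracles, all built in code

fixture_species_tree <- function(topology = "A") {
  read_newick(hypocreales_tree_path(topology), type = "species")
}

# deterministic 10-taxon coalescent-shaped guide tree for RCA tests
rca_test_tree <- function(n = 10, depth_scale = 1) {
  tr <- local({
    set.seed(20240901)
    ape::rcoal(n)
  })
  tr$tip.label <- paste0("s", seq_len(n))
  tr$edge.length <- tr$edge.length * depth_scale
  tr
}

rel_test_tree <- function(n = 6, scale = 0.6) {
  tr <- local({
    set.seed(20240902)
    ape::rcoal(n)
  })
  tr$tip.label <- paste0("s", seq_len(n))
  tr$edge.length <- tr$edge.length * scale
  tr
}

interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1) + 1)
  inter / ((a2 - a1 + 1) + (b2 - b1 + 1) - inter)
}

# --- independent birth-death oracles ---------------------------------------

# truncated generator matrix exponential (independent of the package's
# closed form / eigendecomposition route)
bd_expm_oracle <- function(lambda, t, cap) {
  G <- matrix(0, cap + 1, cap + 1)
  for (s in 1:cap) {
    G[s + 1, s] <- lambda * s
    if (s < cap) G[s + 1, s + 2] <- lambda * s
    G[s + 1, s + 1] <- -2 * lambda * s + if (s == cap) lambda * s else 0
  }
  as.matrix(Matrix::expm(G * t))
}

# brute-force family likelihood by summing over all internal-state
# assignments (trees supplied as ape phylo; prior over 0..cap)
bd_enum_loglik <- function(tree, counts, lambda, cap, root_prior) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  internal <- (ntip + 1):(ntip + tr$Nnode)
  counts <- counts[tr$tip.label]
  grid <- expand.grid(rep(list(0:cap), length(internal)))
  tot <- 0
  P <- lapply(seq_len(nrow(tr$edge)), function(e) {
    vapply(0:cap, function(s) bd_transition_prob(s, 0:cap, lambda,
                                                 tr$edge.length[e]),
           numeric(cap + 1))
  }) # P[[e]][c+1, s+1]
  for (g in seq_len(nrow(grid))) {
    state <- integer(ntip + tr$Nnode)
    state[seq_len(ntip)] <- counts
    state[internal] <- as.integer(grid[g, ])
    pr <- root_prior[state[ntip + 1] + 1]
    if (pr == 0) next
    for (e in seq_len(nrow(tr$edge))) {
      pr <- pr * P[[e]][state[tr$edge[e, 2]] + 1, state[tr$edge[e, 1]] + 1]
      if (pr == 0) break
    }
    tot <- tot + pr
  }
  log(tot)
}

# --- brute-force duplication-loss reconciliation oracle ---------------------

# exhaustive min over all valid mappings via dynamic programming on the
# species tree (Sankoff-style), independent of the LCA construction
brute_reconcile_min <- function(gene_tree, species_tree, dup_cost = 1.5,
                                loss_cost = 1) {
  idx <- famevo:::species_index(species_tree)
  sp_of <- attr(gene_tree, "species") %||%
    famevo:::tip_species(gene_tree$tip.label)
  gt <- stats::reorder(gene_tree, "postorder")
  ngtip <- length(gt$tip.label)
  nn <- ngtip + gt$Nnode
  tipmap <- match(unname(sp_of[gt$tip.label]), species_tree$tip.label)
  anc <- function(a, b) { # is a an ancestor of (or equal to) b
    while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
    a == b
  }
  # cost[v, m]: min cost of the subtree at v given v maps to m (Inf when
  # m is not an ancestor-or-equal of the subtree's tip species LCA)
  cost <- matrix(Inf, nn, idx$nnode)
  for (i in seq_len(ngtip)) cost[i, tipmap[i]] <- 0
  kids <- lapply(seq_len(nn), function(v) gt$edge[gt$edge[, 1] == v, 2])
  edge_losses <- function(m, mu, dup) {
    (idx$depth[mu] - idx$depth[m] - 1 + dup)
  }
  # ape numbers internal nodes parents-first; reverse order is postorder
  for (v in rev(seq_len(nn)[-seq_len(ngtip)])) {
    for (m in seq_len(idx$nnode)) {
      ks <- kids[[v]]
      best <- Inf
      for (m1 in seq_len(idx$nnode)) for (m2 in seq_len(idx$nnode)) {
        if (!anc(m, m1) || !anc(m, m2)) next
        c1 <- cost[ks[1], m1]; c2 <- cost[ks[2], m2]
        if (!is.finite(c1) || !is.finite(c2)) next
        # speciation only if the children map into distinct child
        # subtrees of m
        spec_ok <- m1 != m && m2 != m &&
          famevo:::sp_step_child(idx, m, m1) !=
            famevo:::sp_step_child(idx, m, m2)
        dup <- !spec_ok
        ev_cost <- if (dup) dup_cost else 0
        lo <- loss_cost * (edge_losses(m, m1, dup) + edge_losses(m, m2, dup))
        best <- min(best, c1 + c2 + ev_cost + lo)
      }
      cost[v, m] <- best
    }
  }
  min(cost[ngtip + 1, ])
}

# all rooted binary topologies over the given tip labels, as newick strings
all_rooted_topologies <- function(tips) {
  if (length(tips) == 1) return(paste0(tips, ";"))
  trees <- unlist(famevo:::all_resolutions(as.list(tips)))
  unique(paste0(gsub(")100", ")", trees, fixed = TRUE), ";"))
}
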