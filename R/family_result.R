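# Up-down (outside) algorithm for a single family: marginal posterior over
# ancestral family sizes at every internal node, then per-branch calls.

#' Ancestral family sizes and branch expansion/contraction calls
#'
#' Computes, for one family, the max-posterior ancestral count at every
#' internal node (ties broken toward the smaller count and recorded), the
#' per-branch count change, and a two-sided exact tail test on each
#' parent-to-child transition under the birth--death kernel. Branches are
#' flagged significant only when both the branch test and the family-level
#' p-value are at or below `alpha`, mirroring per-lineage expansion and
#' contraction calls on the dated species tree.
#'
#' @param counts named tip-count vector for the family.
#' @param model fitted [bd_model()].
#' @param tree calibrated `dated_species_tree`.
#' @param family_p family-level p-value from [family_p_value()].
#' @param alpha significance level for the flags (default 0.05).
#' @param family_id optional identifier carried into the result.
#' @param root_prior optional root-size prior.
#' @param bh_correct apply Benjamini-Hochberg across this family's branches
#'   before flagging (off by default).
#' @return list of class `family_evolution_result`: `family_id`, `logLik`,
#'   `p_value`, `node_counts` (per node, ape numbering; tips = observed),
#'   `ties` (nodes whose posterior was tied), and `branches` — a data.frame
#'   with `parent_node`, `child_node`, `parent_count`, `child_count`,
#'   `delta`, `branch_p`, `significant`, `direction`.
#' @export
ancestral_counts_and_branch_calls <- function(counts, model, tree, family_p,
                                              alpha = 0.05, family_id = NA,
                                              root_prior = NULL,
                                              bh_correct = FALSE) {
  cap <- model$count_cap
  lambda <- model$lambda_rate
  if (is.null(root_prior)) root_prior <- uniform_root_prior(cap)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  counts <- counts[tr$tip.label]
  if (any(is.na(counts))) stop("every tip needs a count")
  mats <- edge_transition_matrices(tr, lambda, cap)

  # up pass: partial likelihood vectors (unscaled relative values suffice)
  up <- vector("list", nnode)     # partial likelihood of node's subtree
  upmsg <- vector("list", nrow(tr$edge)) # message from child through edge
  for (i in seq_len(ntip)) {
    v <- numeric(cap + 1); v[counts[i] + 1L] <- 1
    up[[i]] <- v
  }
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    msg <- as.vector(mats[[e]] %*% up[[ch]])
    if (max(msg) > 0) msg <- msg / max(msg)
    upmsg[[e]] <- msg
    up[[p]] <- if (is.null(up[[p]])) msg else up[[p]] * msg
  }
  root <- ntip + 1L

  # down pass in preorder (reverse postorder edge sequence)
  down <- vector("list", nnode)
  down[[root]] <- root_prior
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sib_edges <- setdiff(which(tr$edge[, 1] == p), e)
    above <- down[[p]]
    for (se in sib_edges) above <- above * upmsg[[se]]
    d <- as.vector(above %*% mats[[e]])
    if (max(d) > 0) d <- d / max(d)
    down[[ch]] <- d
  }

  node_counts <- integer(nnode)
  node_counts[seq_len(ntip)] <- counts
  ties <- integer(0)
  for (v in (ntip + 1L):nnode) {
    post <- up[[v]] * down[[v]]
    if (sum(post) == 0) stop("zero posterior at node ", v,
                             " (data impossible under model)")
    best <- which(post == max(post)) - 1L
    if (length(best) > 1L) ties <- c(ties, v)
    node_counts[v] <- min(best)
  }

  ll <- bd_family_loglik(tree, counts, lambda, cap = cap,
                         root_prior = root_prior)
  br <- data.frame(parent_node = tr$edge[, 1], child_node = tr$edge[, 2])
  br$parent_count <- node_counts[br$parent_node]
  br$child_count <- node_counts[br$child_node]
  br$delta <- br$child_count - br$parent_count
  br$branch_p <- mapply(function(s, d, t) bd_branch_tail(s, d, lambda, t),
                        br$parent_count, br$delta, tr$edge.length)
  p_for_flag <- if (bh_correct) stats::p.adjust(br$branch_p, "BH") else br$branch_p
  br$significant <- family_p <= alpha & p_for_flag <= alpha & br$delta != 0
  br$direction <- ifelse(br$delta > 0, "expansion",
                         ifelse(br$delta < 0, "contraction", "none"))
  node_lab <- c(tr$tip.label, paste0("node", (ntip + 1L):nnode))
  br$parent_label <- node_lab[br$parent_node]
  br$child_label <- node_lab[br$child_node]

  structure(list(family_id = family_id, logLik = ll, p_value = family_p,
                 node_counts = setNames(node_counts, node_lab),
                 ties = ties, branches = br),
            class = "family_evolution_result")
}

# two-sided exact tail: probability of a parent->child change at least as
# extreme (in absolute size difference) as the observed delta
bd_branch_tail <- function(s, delta, lambda, t) {
  if (delta == 0) return(1)
  d <- abs(delta)
  cap <- 50L * as.integer(ceiling(max(4 * s + 20, s + 2 * d + 20) / 50))
  p_row <- bd_transition_matrix(lambda, t, cap)[s + 1, ]
  lower <- if (s - d >= 0) sum(p_row[seq_len(s - d + 1)]) else 0
  upper <- sum(p_row[(s + d + 1):(cap + 1)]) + max(0, 1 - sum(p_row))
  min(1, lower + upper)
}
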