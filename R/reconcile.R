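# Duplication-loss reconciliation of rooted gene trees against a rooted
# species tree, with NOTUNG-style weighted event costs (1.5 per duplication,
# 1 per loss by default) and bootstrap-threshold rearrangement.

species_index <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  nnode <- ntip + species_tree$Nnode
  parent <- integer(nnode)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  root <- ntip + 1L
  parent[root] <- 0L
  depth <- integer(nnode)
  tr <- stats::reorder(species_tree, "postorder")
  for (e in rev(seq_len(nrow(tr$edge)))) {
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + 1L
  }
  children <- lapply(seq_len(nnode), function(v) {
    species_tree$edge[species_tree$edge[, 1] == v, 2]
  })
  labels <- c(species_tree$tip.label, paste0("node", (ntip + 1L):nnode))
  list(ntip = ntip, nnode = nnode, root = root, parent = parent,
       depth = depth, children = children, labels = labels,
       newick = ape::write.tree(species_tree))
}

sp_lca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] > idx$depth[b]) a <- idx$parent[a]
    else if (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
    else { a <- idx$parent[a]; b <- idx$parent[b] }
  }
  a
}

# which child of ancestor `a` lies on the path toward descendant `b`
sp_step_child <- function(idx, a, b) {
  while (idx$parent[b] != a) b <- idx$parent[b]
  b
}

#' LCA duplication--loss reconciliation
#'
#' Maps every gene-tree node to the most recent common ancestor (in the
#' species tree) of the species of its descendant tips. A node is a
#' duplication when its mapping coincides with a child's mapping; losses are
#' counted for every species-tree node silently passed between a parent and
#' child mapping, and attributed to the species branch of the lineage that
#' failed to survive. The LCA mapping minimizes the duplication count over
#' all reconciliations; losses above the species root are not counted.
#'
#' @param gene_tree a rooted `gene_tree` (see [as_gene_tree()]).
#' @param species_tree a rooted `dated_species_tree` (any rooted `phylo`
#'   works).
#' @param dup_cost,loss_cost event weights (defaults 1.5 and 1).
#' @return list of class `reconciliation`: `events` (per gene node: event
#'   label and mapped species node), `loss_branches` (per species node:
#'   losses on the branch above it), totals `D` and `L`, weighted `cost`,
#'   and a per-species-lineage attribution table.
#' @export
lca_reconcile <- function(gene_tree, species_tree, dup_cost = 1.5,
                          loss_cost = 1) {
  idx <- species_index(species_tree)
  sp_of <- attr(gene_tree, "species") %||% tip_species(gene_tree$tip.label)
  gt <- stats::reorder(gene_tree, "postorder")
  tipmap <- match(unname(sp_of[gt$tip.label]), species_tree$tip.label)
  if (any(is.na(tipmap))) {
    bad <- gt$tip.label[is.na(tipmap)]
    stop("gene tips map to species absent from the species tree: ",
         paste(bad, collapse = ", "))
  }
  ngtip <- length(gt$tip.label)
  ngnode <- ngtip + gt$Nnode
  M <- integer(ngnode)
  M[seq_len(ngtip)] <- tipmap
  kids <- lapply(seq_len(ngnode), function(v) gt$edge[gt$edge[, 1] == v, 2])
  for (e in seq_len(nrow(gt$edge))) {
    p <- gt$edge[e, 1]; ch <- gt$edge[e, 2]
    M[p] <- if (M[p] == 0L) M[ch] else sp_lca(idx, M[p], M[ch])
  }
  event <- rep("leaf", ngnode)
  loss_branches <- integer(idx$nnode)
  dup_at <- integer(idx$nnode)
  D <- 0L; L <- 0L
  for (v in seq_len(ngnode)[-seq_len(ngtip)]) {
    cm <- M[kids[[v]]]
    is_dup <- any(cm == M[v])
    event[v] <- if (is_dup) "duplication" else "speciation"
    if (is_dup) { D <- D + 1L; dup_at[M[v]] <- dup_at[M[v]] + 1L }
    for (u in kids[[v]]) {
      a <- M[v]; b <- M[u]
      if (b == a && !is_dup) next
      # the child lineage starts at `a` (duplication) or inside the child
      # branch of `a` leading toward `b` (speciation); every species node
      # it passes without reaching `b` sheds the off-path lineage
      start <- if (is_dup) a else sp_step_child(idx, a, b)
      x <- start
      while (x != b) {
        onpath <- sp_step_child(idx, x, b)
        for (y in setdiff(idx$children[[x]], onpath)) {
          loss_branches[y] <- loss_branches[y] + 1L
          L <- L + 1L
        }
        x <- onpath
      }
    }
  }
  glabels <- c(gt$tip.label, paste0("g", seq_len(ngnode)[-seq_len(ngtip)]))
  events <- data.frame(gene_node = seq_len(ngnode), gene_label = glabels,
                       event = event, species_node = M,
                       species_label = idx$labels[M])
  lineage <- data.frame(species_node = seq_len(idx$nnode),
                        lineage = idx$labels,
                        duplications = dup_at, losses = loss_branches)
  structure(list(events = events, loss_branches = loss_branches,
                 D = D, L = L, cost = dup_cost * D + loss_cost * L,
                 dup_cost = dup_cost, loss_cost = loss_cost,
                 lineage_table = lineage, species_newick = idx$newick,
                 gene_tree = gt),
            class = "reconciliation")
}

# ---- bootstrap-threshold rearrangement -------------------------------------

phylo_to_clade <- function(tree) {
  sup <- gene_tree_supports(tree)
  ntip <- length(tree$tip.label)
  id <- 0L
  build <- function(v) {
    id <<- id + 1L
    my_id <- id
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    if (!length(kids)) return(list(label = tree$tip.label[v], id = my_id))
    list(children = lapply(kids, build),
         support = if (v == ntip + 1L) NA_real_ else sup[v - ntip],
         id = my_id)
  }
  build(ntip + 1L)
}

collapse_weak <- function(clade, threshold, missing_as_full,
                          is_root = TRUE) {
  if (!is.null(clade$label)) return(clade)
  newkids <- list()
  for (ch in clade$children) {
    ch <- collapse_weak(ch, threshold, missing_as_full, is_root = FALSE)
    collapse <- FALSE
    if (is.null(ch$label)) {
      sup <- ch$support %||% NA_real_
      if (is.na(sup)) {
        if (!missing_as_full && threshold > 0) {
          stop("internal edge without bootstrap support; set ",
               "missing_as_full = TRUE to treat missing supports as 100")
        }
        sup <- 100
      }
      collapse <- sup < threshold
    }
    if (collapse) newkids <- c(newkids, ch$children)
    else newkids <- c(newkids, list(ch))
  }
  clade$children <- newkids
  clade
}

# every rooted binary fusion of the fragment strings in `frags`
all_resolutions <- function(frags) {
  join <- function(a, b) paste0("(", a, ",", b, ")100")
  if (length(frags) == 1L) return(frags[[1]])
  insert_all <- function(tr, leaf) {
    out <- list(join(tr, leaf))
    if (!startsWith(tr, "(")) return(out)
    body <- sub("^\\((.*)\\)100$", "\\1", tr)
    depth <- 0L; split_at <- NA_integer_
    chars <- strsplit(body, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") depth <- depth - 1L
      if (chars[i] == "," && depth == 0L) { split_at <- i; break }
    }
    left <- substr(body, 1, split_at - 1)
    right <- substr(body, split_at + 1, nchar(body))
    for (lf in insert_all(left, leaf)) out <- c(out, list(join(lf, right)))
    for (rf in insert_all(right, leaf)) out <- c(out, list(join(left, rf)))
    out
  }
  trees <- list(join(frags[[1]], frags[[2]]))
  for (k in seq_along(frags)[-(1:2)]) {
    trees <- unlist(lapply(trees, insert_all, leaf = frags[[k]]))
  }
  unique(trees)
}

clade_tips <- function(clade) {
  if (!is.null(clade$label)) return(clade$label)
  unlist(lapply(clade$children, clade_tips))
}

# greedy resolution shape over placeholder tokens: repeatedly join the pair
# of children whose species LCA is deepest (most congruent first)
greedy_shape <- function(maps, tokens, idx) {
  frags <- as.list(tokens)
  while (length(frags) > 2L) {
    best <- c(1L, 2L); best_d <- -1L
    for (i in seq_along(frags)) for (j in seq_along(frags)) {
      if (j <= i) next
      d <- idx$depth[sp_lca(idx, maps[i], maps[j])]
      if (d > best_d) { best_d <- d; best <- c(i, j) }
    }
    joined <- paste0("(", frags[[best[1]]], ",", frags[[best[2]]], ")100")
    jm <- sp_lca(idx, maps[best[1]], maps[best[2]])
    frags <- c(frags[-best], list(joined))
    maps <- c(maps[-best], jm)
  }
  paste0("(", frags[[1]], ",", frags[[2]], ")100")
}

#' Collapse weakly supported edges and re-resolve to minimize event cost
#'
#' Gene-tree edges with bootstrap support below `support_threshold`
#' (default 90) are collapsed into polytomies; each polytomy is then
#' re-resolved to minimize the weighted duplication--loss cost against the
#' species tree — exhaustively for polytomies of degree at most
#' `exhaustive_max` (default 6), by greedy deepest-mapping joins beyond.
#' The returned reconciliation never costs more than the input resolution;
#' with `support_threshold = 0` the input is returned unchanged.
#'
#' @inheritParams lca_reconcile
#' @param support_threshold bootstrap percentage below which internal edges
#'   collapse (default 90).
#' @param exhaustive_max largest polytomy degree resolved exhaustively.
#' @param missing_as_full treat missing supports as 100 instead of erroring.
#' @return list with elements `gene_tree` (the chosen resolution) and
#'   `reconciliation`.
#' @export
rearrange_weak_edges <- function(gene_tree, species_tree,
                                 support_threshold = 90,
                                 dup_cost = 1.5, loss_cost = 1,
                                 exhaustive_max = 6,
                                 missing_as_full = FALSE) {
  sp_of <- attr(gene_tree, "species") %||% tip_species(gene_tree$tip.label)
  rec_of <- function(nwk) {
    gt <- read_newick(nwk, type = "gene", species_map = sp_of)
    lca_reconcile(gt, species_tree, dup_cost = dup_cost,
                  loss_cost = loss_cost)
  }
  original <- lca_reconcile(gene_tree, species_tree, dup_cost = dup_cost,
                            loss_cost = loss_cost)
  if (support_threshold <= 0) {
    return(list(gene_tree = original$gene_tree, reconciliation = original))
  }
  idx <- species_index(species_tree)
  clade <- collapse_weak(phylo_to_clade(gene_tree), support_threshold,
                         missing_as_full)

  # species mapping of a tip set (independent of internal resolution)
  map_of_tips <- function(tips) {
    nodes <- match(unname(sp_of[tips]), idx$labels[seq_len(idx$ntip)])
    m <- nodes[1]
    for (n in nodes[-1]) m <- sp_lca(idx, m, n)
    m
  }

  # enumerate candidate shapes per polytomy node (placeholder tokens @i@
  # stand for the polytomy's children)
  polys <- list()
  walk <- function(cl) {
    if (!is.null(cl$label)) return(invisible())
    if (length(cl$children) > 2L) {
      tokens <- paste0("@", cl$id, ".", seq_along(cl$children), "@")
      maps <- vapply(cl$children, function(ch) map_of_tips(clade_tips(ch)),
                     integer(1))
      shapes <- if (length(cl$children) <= exhaustive_max) {
        all_resolutions(as.list(tokens))
      } else {
        list(greedy_shape(maps, tokens, idx))
      }
      polys[[as.character(cl$id)]] <<- list(clade = cl, tokens = tokens,
                                            shapes = shapes)
    }
    for (ch in cl$children) walk(ch)
  }
  walk(clade)

  choices <- lapply(polys, function(p) p$shapes[[1]])
  render <- function(cl) {
    if (!is.null(cl$label)) return(cl$label)
    kid_frags <- vapply(cl$children, render, character(1))
    if (length(cl$children) == 2L) {
      return(paste0("(", kid_frags[1], ",", kid_frags[2], ")",
                    if (is.na(cl$support %||% NA_real_)) ""
                    else format(cl$support)))
    }
    p <- polys[[as.character(cl$id)]]
    frag <- choices[[as.character(cl$id)]]
    for (i in seq_along(p$tokens)) {
      frag <- gsub(p$tokens[i], kid_frags[i], frag, fixed = TRUE)
    }
    frag
  }
  best_rec <- rec_of(paste0(render(clade), ";"))

  for (pass in 1:2) {
    improved <- FALSE
    for (pid in names(polys)) {
      p <- polys[[pid]]
      if (length(p$shapes) == 1L) next
      keep <- choices[[pid]]
      for (shape in p$shapes) {
        choices[[pid]] <- shape
        r <- rec_of(paste0(render(clade), ";"))
        if (r$cost < best_rec$cost - 1e-9) {
          best_rec <- r; keep <- shape; improved <- TRUE
        }
      }
      choices[[pid]] <- keep
    }
    if (!improved) break
  }
  if (original$cost <= best_rec$cost + 1e-9) best_rec <- original
  list(gene_tree = best_rec$gene_tree, reconciliation = best_rec)
}

#' Sum duplication and loss events per species lineage across families
#'
#' @param results a `reconciliation` or list of them, all from the same
#'   species tree.
#' @param species_tree the shared species tree.
#' @return data.frame with `lineage`, `duplications`, `losses` per species
#'   branch (terminal branches named by species, internal by node number).
#' @export
summarize_lineage_events <- function(results, species_tree) {
  idx <- species_index(species_tree)
  if (inherits(results, "reconciliation")) results <- list(results)
  for (r in results) {
    if (!identical(r$species_newick, idx$newick)) {
      stop("reconciliations come from different species trees")
    }
  }
  dup <- Reduce(`+`, lapply(results, function(r) r$lineage_table$duplications))
  los <- Reduce(`+`, lapply(results, function(r) r$lineage_table$losses))
  data.frame(species_node = seq_len(idx$nnode), lineage = idx$labels,
             duplications = dup, losses = los)
}
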