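#' Read a Newick tree
#'
#' Parses a rooted tree from a Newick file. Internal node labels that are
#' numeric are interpreted as bootstrap support percentages when
#' `support_dialect = "label"` (the common dialect); with
#' `support_dialect = "comment"` supports are read from square-bracket
#' comments following internal-node closing parentheses (e.g. `)[95]`).
#'
#' @param path path to a Newick file (or a literal Newick string ending in
#'   `;` for convenience).
#' @param type `"species"` for a dated species tree, `"gene"` for a gene
#'   tree carrying a tip-to-species mapping, or `"auto"` (plain `phylo`).
#' @param support_dialect `"label"` or `"comment"`, see Details.
#' @param species_sep separator used to derive the species name from gene
#'   tip labels (prefix up to the first separator).
#' @param species_map optional named character vector (or two-column
#'   data.frame tip, species) overriding the prefix rule.
#' @return an object of class `phylo`, additionally classed
#'   `dated_species_tree` or `gene_tree`.
#' @export
read_newick <- function(path, type = c("auto", "species", "gene"),
                        support_dialect = c("label", "comment"),
                        species_sep = "_", species_map = NULL) {
  type <- match.arg(type)
  support_dialect <- match.arg(support_dialect)
  txt <- if (grepl("[();]", path) && !file.exists(path)) {
    path
  } else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  txt <- trimws(txt)
  check_newick_syntax(txt)
  if (support_dialect == "comment") {
    txt <- gsub("\\)\\[([0-9.]+)\\]", ")\\1", txt)
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed")
  }
  switch(type,
    auto = tr,
    species = as_dated_species_tree(tr),
    gene = as_gene_tree(tr, species_sep = species_sep,
                        species_map = species_map))
}

# crude syntax check that reports a character offset, since downstream
# parsers fail without position information
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unbalanced ')' at character offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' by character offset ",
         length(chars))
  }
  if (!grepl(";\\s*$", txt)) {
    stop("malformed Newick: missing terminal ';' at character offset ",
         nchar(txt))
  }
  invisible(TRUE)
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` (supports, if any, are written as internal node
#'   labels).
#' @param path output path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname read_newick
#' @param tree a rooted `phylo`.
#' @export
as_dated_species_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) stop("species tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  class(tree) <- unique(c("dated_species_tree", class(tree)))
  tree
}

#' @rdname read_newick
#' @export
as_gene_tree <- function(tree, species_sep = "_", species_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("gene tree must be rooted")
  sp <- tip_species(tree$tip.label, sep = species_sep, map = species_map)
  sup <- gene_tree_supports(tree)
  if (any(!is.na(sup) & (sup < 0 | sup > 100))) {
    stop("bootstrap supports must lie in [0, 100]")
  }
  attr(tree, "species") <- sp
  class(tree) <- unique(c("gene_tree", class(tree)))
  tree
}

tip_species <- function(labels, sep = "_", map = NULL) {
  if (!is.null(map)) {
    if (is.data.frame(map)) map <- setNames(as.character(map[[2]]),
                                            as.character(map[[1]]))
    missing <- setdiff(labels, names(map))
    if (length(missing)) {
      stop("tips missing from species map: ", paste(missing, collapse = ", "))
    }
    return(setNames(unname(map[labels]), labels))
  }
  setNames(sub(paste0(sep, ".*$"), "", labels), labels)
}

gene_tree_supports <- function(tree) {
  # numeric internal node labels read as bootstrap percentages; NA otherwise
  n_int <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n_int))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Node depths and ages of a dated tree
#'
#' Depth is the path length (Myr) from the root; for an ultrametric tree the
#' age of a node is the common tip depth minus its depth.
#'
#' @param tree a `phylo` with branch lengths.
#' @return numeric vector over nodes (tips first, ape numbering).
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

tip_depth_spread <- function(tree) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  c(min = min(d), max = max(d))
}

is_ultrametric_tol <- function(tree, rel_tol = 1e-6) {
  s <- tip_depth_spread(tree)
  if (s["max"] == 0) return(TRUE)
  (s["max"] - s["min"]) / s["max"] <= rel_tol
}

#' Calibrate an ultrametric tree to an absolute node age
#'
#' Rescales every branch length by a single scalar so that the most recent
#' common ancestor of two named tips sits at the requested age (Myr) —
#' e.g. fixing the *H. minnesotensis* / *H. sinensis* split at 29 Myr
#' against the fossil record. Ultrametricity is required (relative
#' tolerance `rel_tol` on tip depths) and preserved exactly.
#'
#' @param tree an ultrametric `phylo`/`dated_species_tree`.
#' @param tips character vector of two tip labels identifying the MRCA.
#' @param age target age of that MRCA, in Myr.
#' @param rel_tol relative ultrametricity tolerance on tip depths.
#' @return the rescaled tree (same class), with attribute
#'   `"calibration_scale"` recording the factor applied.
#' @export
calibrate_tree <- function(tree, tips, age, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), length(tips) == 2L, age > 0)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop("calibration tips not in tree: ", paste(missing, collapse = ", "))
  }
  if (!is_ultrametric_tol(tree, rel_tol)) {
    stop("tree is not ultrametric within relative tolerance ", rel_tol,
         "; refusing to calibrate")
  }
  mrca <- ape::getMRCA(tree, tips)
  d <- node_depths(tree)
  tip_depth <- mean(d[seq_along(tree$tip.label)])
  cur_age <- tip_depth - d[mrca]
  if (cur_age <= 0) stop("MRCA age is zero; cannot calibrate")
  scale <- age / cur_age
  tree$edge.length <- tree$edge.length * scale
  attr(tree, "calibration_scale") <- scale
  tree
}
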