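# Seeded forward simulators, one per analysis stage. Every generator is a
# pure function of its arguments (seed included), returns its ground truth
# in a manifest, and writes the same formats the analysis functions read.

new_manifest <- function(generator, seed, params, ground_truth) {
  structure(list(generator = generator, seed = seed, params = params,
                 ground_truth = ground_truth),
            class = "simulation_manifest")
}

# exact event-driven (Gillespie) linear birth-death along one branch
gillespie_bd <- function(n0, lambda, t) {
  n <- n0
  time <- 0
  if (lambda == 0) return(n)
  repeat {
    if (n == 0) return(0L)
    wait <- rexp(1, rate = 2 * lambda * n)
    time <- time + wait
    if (time > t) return(n)
    n <- n + sample(c(1L, -1L), 1)
  }
}

#' Simulate gene family counts under the birth--death model
#'
#' For each family the root size is drawn from `root_prior` and evolved
#' down every branch of the dated tree by exact event-driven simulation of
#' the linear birth--death process at rate `lambda` per gene per Myr.
#'
#' @param tree calibrated `dated_species_tree`.
#' @param lambda gain/loss rate (`>= 0`).
#' @param n_families number of families.
#' @param root_prior probability vector over root sizes 0..(length-1);
#'   default uniform over 1..10.
#' @param seed integer seed.
#' @return list with `table` (a `family_count_table`) and `manifest`
#'   (ground truth: `lambda`, per-family root sizes and all node states).
#' @export
simulate_family_counts <- function(tree, lambda, n_families,
                                   root_prior = NULL, seed = 1) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (is.null(root_prior)) root_prior <- c(0, rep(0.1, 10))
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  states <- local_seed(derive_seed(seed, 0), {
    st <- matrix(NA_integer_, n_families, nnode)
    st[, ntip + 1L] <- sample.int(length(root_prior), n_families,
                                  replace = TRUE, prob = root_prior) - 1L
    for (e in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      st[, ch] <- vapply(st[, p], gillespie_bd, integer(1),
                         lambda = lambda, t = tr$edge.length[e])
    }
    st
  })
  tab <- as.data.frame(states[, seq_len(ntip), drop = FALSE])
  names(tab) <- tr$tip.label
  tab <- cbind(family_id = sprintf("FAM%04d", seq_len(n_families)), tab)
  list(table = as_family_count_table(tab),
       manifest = new_manifest("simulate_family_counts", seed,
                               list(lambda = lambda,
                                    n_families = n_families,
                                    root_prior = root_prior),
                               list(node_states = states,
                                    root_sizes = states[, ntip + 1L])))
}

#' Simulate a gene tree by duplication and loss inside a species tree
#'
#' A single gene lineage enters at the species root; along every species
#' branch it duplicates at `dup_rate` and dies at `loss_rate` (events per
#' lineage per Myr), and splits with each speciation. Lineages without
#' surviving descendants are pruned. Supports are 100 by default and can be
#' degraded with `support_noise` (sd of a downward Gaussian kick).
#'
#' @param species_tree rooted `dated_species_tree`.
#' @param dup_rate,loss_rate event rates (`>= 0`).
#' @param seed integer seed.
#' @param support_noise sd of support degradation (0 = all 100).
#' @param max_retry attempts before giving up when everything dies.
#' @return list with `gene_tree` (a `gene_tree`; tips `<species>_g<k>`),
#'   and `manifest` (ground truth: surviving duplication count `true_D`,
#'   loss events `true_L`, per-species-branch duplication placements).
#' @export
simulate_gene_tree <- function(species_tree, dup_rate, loss_rate, seed = 1,
                               support_noise = 0, max_retry = 100) {
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be non-negative")
  idx <- species_index(species_tree)
  lens <- numeric(idx$nnode)
  lens[species_tree$edge[, 2]] <- species_tree$edge.length
  for (attempt in seq_len(max_retry)) {
    res <- local_seed(derive_seed(seed, attempt - 1L),
                      sim_gene_tree_once(species_tree, idx, lens, dup_rate,
                                         loss_rate, support_noise))
    if (!is.null(res)) {
      gt <- read_newick(res$newick, type = "gene")
      return(list(gene_tree = gt,
                  manifest = new_manifest("simulate_gene_tree", seed,
                    list(dup_rate = dup_rate, loss_rate = loss_rate,
                         support_noise = support_noise,
                         attempt = attempt),
                    list(true_D = res$true_D, true_L = res$true_L,
                         dup_branches = res$dup_branches))))
    }
  }
  stop("all gene lineages went extinct in ", max_retry, " attempts")
}

sim_gene_tree_once <- function(sp, idx, lens, dup_rate, loss_rate,
                               support_noise) {
  counter <- new.env()
  counter$n <- setNames(integer(idx$ntip), sp$tip.label)
  counter$losses <- 0L
  counter$dups <- integer(idx$nnode) # surviving duplications per branch
  total <- dup_rate + loss_rate
  sup <- function() {
    if (support_noise <= 0) 100
    else max(0, min(100, round(100 - abs(rnorm(1, 0, support_noise)))))
  }
  # returns list(newick fragment, n_tips) or NULL when extinct
  at_node <- function(v) {
    kids <- idx$children[[v]]
    if (!length(kids)) {
      spn <- idx$labels[v]
      counter$n[spn] <- counter$n[spn] + 1L
      return(list(frag = paste0(spn, "_g", counter$n[spn]), tips = 1L))
    }
    parts <- list()
    for (ch in kids) {
      r <- along_edge(ch, lens[ch])
      if (!is.null(r)) parts <- c(parts, list(r))
    }
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L) return(parts[[1]])
    list(frag = paste0("(", parts[[1]]$frag, ",", parts[[2]]$frag, ")",
                       sup()),
         tips = parts[[1]]$tips + parts[[2]]$tips)
  }
  along_edge <- function(target, t_left) {
    if (total > 0) {
      wait <- rexp(1, total)
      if (wait < t_left) {
        if (runif(1) < loss_rate / total) {
          counter$losses <- counter$losses + 1L
          return(NULL)
        }
        a <- along_edge(target, t_left - wait)
        b <- along_edge(target, t_left - wait)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        counter$dups[target] <- counter$dups[target] + 1L
        return(list(frag = paste0("(", a$frag, ",", b$frag, ")", sup()),
                    tips = a$tips + b$tips))
      }
    }
    at_node(target)
  }
  root_res <- at_node(idx$root)
  if (is.null(root_res) || root_res$tips < 2L) return(NULL)
  frag <- root_res$frag
  if (!startsWith(frag, "(")) return(NULL)
  list(newick = paste0(frag, ";"),
       true_D = sum(counter$dups), true_L = counter$losses,
       dup_branches = setNames(counter$dups, idx$labels))
}

#' Simulate a protein alignment with planted rate-variable blocks
#'
#' Sequences evolve down `tree` under the empirical amino-acid model; each
#' column's rate is the base rate times its block multiplier (columns
#' outside any block have multiplier 1). Ground-truth block coordinates are
#' recorded for recovery scoring.
#'
#' @param tree `phylo` with branch lengths (substitutions/site).
#' @param n_columns alignment length.
#' @param block_spec data.frame with `start`, `end`, `rate_multiplier`
#'   (1-based inclusive alignment columns; non-overlapping).
#' @param model amino-acid model name (default `"JTT"`).
#' @param seed integer seed.
#' @return list with `alignment` (an `aa_alignment`) and `manifest`.
#' @export
simulate_region_alignment <- function(tree, n_columns, block_spec = NULL,
                                      model = "JTT", seed = 1) {
  if (is.null(block_spec)) {
    block_spec <- data.frame(start = integer(0), end = integer(0),
                             rate_multiplier = numeric(0))
  }
  if (nrow(block_spec)) {
    if (any(block_spec$start < 1 | block_spec$end > n_columns |
              block_spec$start > block_spec$end)) {
      stop("block out of bounds")
    }
    cov <- unlist(mapply(seq, block_spec$start, block_spec$end,
                         SIMPLIFY = FALSE))
    if (anyDuplicated(cov)) stop("overlapping blocks")
  }
  rates <- rep(1, n_columns)
  for (i in seq_len(nrow(block_spec))) {
    rates[block_spec$start[i]:block_spec$end[i]] <- block_spec$rate_multiplier[i]
  }
  md <- aa_model_data(model)
  q <- make_q_matrix(md$exchangeability, md$pi)
  aln <- local_seed(derive_seed(seed, 0),
                    evolve_states(tree, q, md$pi, rates))
  chars <- matrix(md$states[aln], nrow(aln), ncol(aln),
                  dimnames = dimnames(aln))
  list(alignment = as_alignment(setNames(apply(chars, 1, paste,
                                               collapse = ""),
                                         rownames(chars)),
                                type = "protein"),
       manifest = new_manifest("simulate_region_alignment", seed,
                               list(n_columns = n_columns, model = model),
                               list(blocks = block_spec,
                                    column_rates = rates)))
}

# evolve discrete states down a tree: per-column rate multipliers share
# eigendecompositions per unique rate; returns tips x columns index matrix
evolve_states <- function(tree, q, pi, rates) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  fac <- pmat_factory(q, pi)
  ncolumns <- length(rates)
  urates <- unique(rates)
  rate_id <- match(rates, urates)
  states <- matrix(NA_integer_, nnode, ncolumns)
  states[ntip + 1L, ] <- sample.int(length(pi), ncolumns, replace = TRUE,
                                    prob = pi)
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    for (ri in seq_along(urates)) {
      cols <- which(rate_id == ri)
      if (!length(cols)) next
      P <- fac(urates[ri] * tr$edge.length[e])
      ps <- states[p, cols]
      out <- integer(length(cols))
      for (s in unique(ps)) {
        ii <- which(ps == s)
        out[ii] <- sample.int(ncol(P), length(ii), replace = TRUE,
                              prob = pmax(P[s, ], 0))
      }
      states[ch, cols] <- out
    }
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tr$tip.label
  out
}

#' Simulate an in-frame codon alignment with site-class dN/dS mixture
#'
#' Sites are assigned to classes in the given fractions (ground truth
#' recorded) and evolve under the MG94-style codon model with the declared
#' nucleotide exchangeability pattern.
#'
#' @param tree `phylo` with branch lengths (expected neutral substitutions
#'   per codon).
#' @param n_codons number of codon sites.
#' @param site_class_spec data.frame with `fraction`, `dN`, `dS` (fractions
#'   sum to 1).
#' @param model_params list with `R` (AT, CT, GT exchangeabilities) and
#'   optionally `pos_freqs` (3 x 4 positional base frequencies).
#' @param seed integer seed.
#' @return list with `alignment` (a `codon_alignment`) and `manifest`
#'   (per-site true class).
#' @export
simulate_codon_alignment <- function(tree, n_codons, site_class_spec,
                                     model_params = list(R = c(1, 1, 1)),
                                     seed = 1) {
  if (abs(sum(site_class_spec$fraction) - 1) > 1e-8) {
    stop("class fractions must sum to 1")
  }
  pos_freqs <- model_params$pos_freqs %||%
    matrix(0.25, 3, 4, dimnames = list(NULL, NT))
  st <- mg94_structure(model_params$R, pos_freqs)
  k <- nrow(site_class_spec)
  n_per <- floor(site_class_spec$fraction * n_codons)
  while (sum(n_per) < n_codons) {
    i <- which.max(site_class_spec$fraction * n_codons - n_per)
    n_per[i] <- n_per[i] + 1L
  }
  classes <- local_seed(derive_seed(seed, 1),
                        sample(rep(seq_len(k), n_per)))
  # per-class rate matrices share one state space; evolve class by class
  cods <- sense_codons()
  tips <- NULL
  aln <- matrix(NA_integer_, length(tree$tip.label), n_codons,
                dimnames = list(stats::reorder(tree, "postorder")$tip.label,
                                NULL))
  for (ci in seq_len(k)) {
    cols <- which(classes == ci)
    if (!length(cols)) next
    q <- mg94_q(st, site_class_spec$dS[ci], site_class_spec$dN[ci])
    sim <- local_seed(derive_seed(seed, 10 + ci),
                      evolve_states(tree, q, st$pi_codon,
                                    rep(1, length(cols))))
    aln[rownames(sim), cols] <- sim
  }
  seqs <- apply(aln, 1, function(ix) paste(cods[ix], collapse = ""))
  list(alignment = as_alignment(seqs, type = "codon"),
       manifest = new_manifest("simulate_codon_alignment", seed,
                               list(n_codons = n_codons,
                                    site_class_spec = site_class_spec,
                                    model_params = model_params),
                               list(site_class = classes)))
}

#' Simulate a replicated qPCR Ct table with planted fold changes
#'
#' Reference-gene Ct values are Normal(20, sigma); target Ct equals the
#' reference plus a baseline dCt minus log2(fold change), plus independent
#' Gaussian noise. `NA` entries of the fold-change matrix become
#' non-detectable (`N/D`) records. Two identical technical replicates are
#' emitted per biological replicate (technical structure beyond averaging
#' is not simulated).
#'
#' @param genes character vector of gene ids.
#' @param treatments character vector (first is conventionally the
#'   control, whose fold changes should be 1).
#' @param fold_change_matrix genes x treatments matrix of true fold
#'   changes (> 0, or NA for N/D).
#' @param n_bio_reps biological replicates per cell (default 5).
#' @param sigma Ct noise sd (default 0.15).
#' @param baseline_dct baseline target-minus-reference Ct (default 3).
#' @param seed integer seed.
#' @return list with `records` (Ct table data.frame) and `manifest`.
#' @export
simulate_ct_table <- function(genes, treatments, fold_change_matrix,
                              n_bio_reps = 5, sigma = 0.15,
                              baseline_dct = 3, seed = 1) {
  if (sigma < 0) stop("sigma must be non-negative")
  fc <- fold_change_matrix
  if (any(!is.na(fc) & fc <= 0)) stop("fold changes must be positive or NA")
  rows <- local_seed(derive_seed(seed, 0), {
    out <- list()
    for (gi in seq_along(genes)) for (ti in seq_along(treatments)) {
      for (b in seq_len(n_bio_reps)) {
        ct_ref <- rnorm(1, 20, sigma)
        if (is.na(fc[gi, ti])) {
          ct_tar <- NA_real_
          det <- FALSE
        } else {
          ct_tar <- ct_ref + baseline_dct - log2(fc[gi, ti]) +
            rnorm(1, 0, sigma)
          det <- TRUE
        }
        for (tech in 1:2) {
          out[[length(out) + 1L]] <- data.frame(
            gene = genes[gi], treatment = treatments[ti], bio_rep = b,
            tech_rep = tech, ct_target = ct_tar, ct_reference = ct_ref,
            detectable = det)
        }
      }
    }
    do.call(rbind, out)
  })
  list(records = rows,
       manifest = new_manifest("simulate_ct_table", seed,
                               list(n_bio_reps = n_bio_reps, sigma = sigma,
                                    baseline_dct = baseline_dct),
                               list(fold_changes = fc)))
}
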