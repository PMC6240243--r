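# Orchestration: subcommands mirroring the analysis stages, each writing
# its module's TSV outputs plus a JSON run manifest. A thin Rscript wrapper
# lives in inst/cli/famevo.R; run_famevo() is the programmatic entry point.

famevo_defaults <- function() {
  list(window_n = 7, intensity = 0.5, dup_cost = 1.5, loss_cost = 1,
       bootstrap_cutoff = 90, bf_strong = 50, bf_weak_low = 10,
       alpha = 0.05, max_gap_fraction = 0.5, n_null = 1000, seed = 1)
}

parse_argv <- function(argv) {
  if (!length(argv)) return(list(subcommand = NA_character_, opts = list()))
  sub <- argv[1]
  opts <- list()
  i <- 2
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key)
    key <- sub("^--", "", key)
    if (i + 1 > length(argv)) stop("missing value for --", key)
    val <- argv[i + 1]
    opts[[gsub("-", "_", key)]] <- val
    i <- i + 2
  }
  list(subcommand = sub, opts = opts)
}

merge_config <- function(opts) {
  cfg <- famevo_defaults()
  if (!is.null(opts$config)) {
    file_cfg <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    cfg[names(file_cfg)] <- file_cfg
    opts$config <- NULL
  }
  for (k in names(opts)) {
    v <- opts[[k]]
    suppressWarnings(num <- as.numeric(v))
    cfg[[k]] <- if (!is.na(num)) num else v
  }
  cfg
}

write_manifest <- function(out_dir, subcommand, cfg, inputs = character(0),
                           extra = list()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- c(list(tool = "famevo",
                     version = as.character(utils::packageVersion("famevo")),
                     subcommand = subcommand,
                     parameters = cfg[order(names(cfg))],
                     input_md5 = hashes), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run a famevo pipeline subcommand
#'
#' Subcommands: `counts` (birth--death family analysis), `reconcile`
#' (duplication--loss reconciliation), `rca` (two-group reverse
#' conservation analysis), `rel` (site-selection scan), `qpcr` (ddCt +
#' ANOVA/LSD), `simulate` (synthetic data). Every numeric default is the
#' analysis default (window 7, I = 0.5, costs 1.5/1, cutoff 90, Bayes
#' factor 50 and 10--49, alpha = 0.05, gap mask 0.5); a JSON config file
#' (`--config`) and command-line flags (flags win) override them. Each run
#' writes its outputs plus `manifest.json` into `--out`.
#'
#' @param argv character vector, e.g.
#'   `c("counts", "--counts", "fam.tsv", "--tree", "sp.nwk", "--out", "d")`.
#' @return integer exit status: 0 success, 2 invalid configuration or
#'   missing input, 1 stage failure.
#' @export
run_famevo <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parse_argv(argv), error = function(e) e)
  if (inherits(parsed, "error")) {
    message("famevo: ", conditionMessage(parsed))
    return(2L)
  }
  sub <- parsed$subcommand
  handlers <- list(counts = famevo_counts, reconcile = famevo_reconcile,
                   rca = famevo_rca, rel = famevo_rel, qpcr = famevo_qpcr,
                   simulate = famevo_simulate)
  if (is.na(sub) || !sub %in% names(handlers)) {
    message("famevo: usage: famevo <",
            paste(names(handlers), collapse = "|"), "> [--flag value ...]")
    return(2L)
  }
  cfg <- tryCatch(merge_config(parsed$opts), error = function(e) e)
  if (inherits(cfg, "error")) {
    message("famevo: ", conditionMessage(cfg))
    return(2L)
  }
  if (is.null(cfg$out)) {
    message("famevo: --out is required")
    return(2L)
  }
  inputs <- unlist(cfg[names(cfg) %in%
                         c("counts", "tree", "genetree", "aln_a", "aln_b",
                           "aln", "ct", "map")])
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    message("famevo: missing input file(s): ",
            paste(missing, collapse = ", "))
    return(2L)
  }
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch({
    handlers[[sub]](cfg)
    0L
  }, error = function(e) {
    message("famevo ", sub, ": ", conditionMessage(e))
    # remove partial outputs so failed runs leave nothing behind
    unlink(list.files(cfg$out, full.names = TRUE), recursive = TRUE)
    1L
  })
  res
}

famevo_counts <- function(cfg) {
  tree <- read_newick(cfg$tree, type = "species")
  tab <- filter_families(read_family_counts(cfg$counts))
  model <- if (!is.null(cfg$lambda)) {
    m <- count_matrix(tab, species = tree$tip.label)
    bd_model(as.numeric(cfg$lambda), default_cap(max(m)))
  } else {
    estimate_lambda(tab, tree)
  }
  cm <- count_matrix(tab, species = tree$tip.label)
  pvals <- family_p_values(cm, model, tree, n_null = cfg$n_null,
                           seed = cfg$seed)
  ll <- bd_family_loglik(tree, cm, model$lambda_rate, cap = model$count_cap)
  fam <- data.frame(family_id = tab$family_id, logL = ll, p_value = pvals)
  branches <- do.call(rbind, lapply(seq_len(nrow(cm)), function(i) {
    r <- ancestral_counts_and_branch_calls(cm[i, ], model, tree, pvals[i],
                                           alpha = cfg$alpha,
                                           family_id = tab$family_id[i])
    cbind(family_id = tab$family_id[i],
          r$branches[, c("parent_label", "child_label", "parent_count",
                         "child_count", "branch_p", "direction",
                         "significant")])
  }))
  write_tsv(fam, file.path(cfg$out, "families.tsv"))
  write_tsv(branches, file.path(cfg$out, "branches.tsv"))
  write_manifest(cfg$out, "counts", cfg, c(cfg$counts, cfg$tree),
                 list(lambda = model$lambda_rate,
                      count_cap = model$count_cap,
                      logLik = model$logLik,
                      boundary_warning = model$boundary_warning))
}

famevo_reconcile <- function(cfg) {
  sp <- read_newick(cfg$tree, type = "species")
  map <- if (!is.null(cfg$map)) read.delim(cfg$map) else NULL
  gt <- read_newick(cfg$genetree, type = "gene", species_map = map)
  res <- rearrange_weak_edges(gt, sp,
                              support_threshold = cfg$bootstrap_cutoff,
                              dup_cost = cfg$dup_cost,
                              loss_cost = cfg$loss_cost,
                              missing_as_full = TRUE)
  rec <- res$reconciliation
  write_tsv(rec$events, file.path(cfg$out, "events.tsv"))
  write_tsv(summarize_lineage_events(rec, sp),
            file.path(cfg$out, "lineage_summary.tsv"))
  writeLines(write_newick(res$gene_tree),
             file.path(cfg$out, "gene_tree_rearranged.nwk"))
  write_manifest(cfg$out, "reconcile", cfg, c(cfg$genetree, cfg$tree),
                 list(D = rec$D, L = rec$L, cost = rec$cost))
}

famevo_rca <- function(cfg) {
  aln_a <- read_alignment(cfg$aln_a)
  aln_b <- read_alignment(cfg$aln_b)
  profile_of <- function(aln) {
    mask <- mask_gappy_columns(aln, cfg$max_gap_fraction)
    raw <- site_rates(aln)
    normalize_and_window(raw, mask, n = cfg$window_n,
                         map = map_to_reference(aln, cfg$ref))
  }
  pa <- profile_of(aln_a)
  pb <- profile_of(aln_b)
  calls <- call_divergent_regions(pa, pb, I = cfg$intensity)
  write_tsv(pa$columns, file.path(cfg$out, "profile_groupA.tsv"))
  write_tsv(pb$columns, file.path(cfg$out, "profile_groupB.tsv"))
  write_tsv(calls, file.path(cfg$out, "regions.tsv"))
  write_manifest(cfg$out, "rca", cfg, c(cfg$aln_a, cfg$aln_b),
                 list(n_regions = nrow(calls)))
}

famevo_rel <- function(cfg) {
  aln <- read_alignment(cfg$aln, type = "codon")
  tree <- read_newick(cfg$tree)
  fit <- fit_rel_model(aln, tree, seed = cfg$seed,
                       n_restarts = cfg$n_restarts %||% 1,
                       max_iter = cfg$max_iter %||% 10)
  bf <- site_bayes_factors(fit, aln)
  cls <- classify_sites(bf, strong = cfg$bf_strong,
                        weak_low = cfg$bf_weak_low)
  write_tsv(as.data.frame(cls), file.path(cfg$out, "sites.tsv"))
  jsonlite::write_json(list(R = as.list(fit$R), scale = fit$scale,
                            ds_values = fit$ds_values,
                            ds_weights = fit$ds_weights,
                            dn_values = fit$dn_values,
                            dn_weights = fit$dn_weights,
                            logLik = fit$logLik),
                       file.path(cfg$out, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg$out, "rel", cfg, c(cfg$aln, cfg$tree),
                 list(counts = as.list(attr(cls, "counts"))))
}

famevo_qpcr <- function(cfg) {
  records <- read.delim(cfg$ct)
  if (!is.null(cfg$exclude)) {
    records <- exclude_replicates(records, read.delim(cfg$exclude))
  }
  genes <- unique(records$gene)
  rows <- list()
  anova_rows <- list()
  for (g in genes) {
    dd <- ddct(records, g, cfg$control)
    res <- anova_lsd(dd, alpha = cfg$alpha)
    s <- res$summary
    s$gene <- g
    rows[[g]] <- s
    anova_rows[[g]] <- data.frame(gene = g, anova_p = res$anova_p,
                                  skipped = res$skipped)
  }
  write_tsv(do.call(rbind, rows), file.path(cfg$out, "expression.tsv"))
  write_tsv(do.call(rbind, anova_rows), file.path(cfg$out, "anova.tsv"))
  write_manifest(cfg$out, "qpcr", cfg, cfg$ct)
}

famevo_simulate <- function(cfg) {
  kind <- cfg$kind %||% "counts"
  tree <- read_newick(cfg$tree, type = "species")
  if (kind == "counts") {
    sim <- simulate_family_counts(tree, lambda = cfg$lambda %||% 0.017,
                                  n_families = cfg$n_families %||% 500,
                                  seed = cfg$seed)
    write_family_counts(sim$table, file.path(cfg$out, "family_counts.tsv"))
  } else if (kind == "genetree") {
    sim <- simulate_gene_tree(tree, dup_rate = cfg$dup_rate %||% 0.01,
                              loss_rate = cfg$loss_rate %||% 0.005,
                              seed = cfg$seed)
    writeLines(write_newick(sim$gene_tree),
               file.path(cfg$out, "gene_tree.nwk"))
  } else {
    stop("unknown simulation kind: ", kind)
  }
  write_manifest(cfg$out, "simulate", cfg, cfg$tree,
                 list(generator = sim$manifest$generator,
                      ground_truth_summary =
                        lapply(sim$manifest$ground_truth, function(x) {
                          if (is.numeric(x) && length(x) == 1) x else NULL
                        })))
}

#' Path to the bundled synthetic 11-taxon Hypocreales species trees
#'
#' Two alternative topologies (A: *C. rosea* sister to the *Fusaria*;
#' B: *C. rosea* basal in Hypocreales), with synthetic Myr branch lengths
#' consistent with a 29-Myr *H. minnesotensis*/*H. sinensis* calibration.
#'
#' @param topology `"A"` or `"B"`.
#' @return file path of the Newick fixture.
#' @export
hypocreales_tree_path <- function(topology = c("A", "B")) {
  topology <- match.arg(topology)
  system.file("extdata",
              paste0("hypocreales_tree_", topology, "_synthetic.nwk"),
              package = "famevo", mustWork = TRUE)
}
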