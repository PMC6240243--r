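AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")
GAP_CHARS <- c("-", ".")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read an aligned FASTA file
#'
#' Sequences must all have the same length. Protein alignments are validated
#' against the 20-letter amino-acid alphabet (plus `X` for ambiguity and
#' `-`/`.` gaps); codon alignments must be in frame (length divisible by 3)
#' with no internal stop codon in any gap-free codon.
#'
#' @param path FASTA file path.
#' @param type `"protein"` or `"codon"`.
#' @return a character matrix (sequences x columns, uppercase) of class
#'   `aa_alignment` or `codon_alignment`.
#' @export
read_alignment <- function(path, type = c("protein", "codon")) {
  type <- match.arg(type)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  names(seqs) <- ids
  as_alignment(seqs, type = type)
}

#' @rdname read_alignment
#' @param seqs named character vector of equal-length aligned sequences.
#' @export
as_alignment <- function(seqs, type = c("protein", "codon")) {
  type <- match.arg(type)
  if (is.null(names(seqs)) && length(seqs)) stop("sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  seqs <- toupper(gsub("\\s", "", seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("aligned sequences must have equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  ncol <- if (length(lens)) lens[[1]] else 0L
  m <- matrix("", nrow = length(seqs), ncol = ncol,
              dimnames = list(names(seqs), NULL))
  if (ncol > 0) {
    for (i in seq_along(seqs)) m[i, ] <- strsplit(seqs[[i]], "")[[1]]
  }
  if (type == "protein") {
    bad <- setdiff(unique(as.vector(m)), c(AA_ALPHABET, "X", GAP_CHARS))
    if (length(bad)) stop("invalid amino-acid characters: ",
                          paste(bad, collapse = " "))
    class(m) <- c("aa_alignment", class(m))
  } else {
    m[m == "U"] <- "T"
    bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", GAP_CHARS))
    if (length(bad)) stop("invalid nucleotide characters: ",
                          paste(bad, collapse = " "))
    if (ncol %% 3 != 0) stop("codon alignment length ", ncol,
                             " is not divisible by 3")
    check_stop_codons(m)
    class(m) <- c("codon_alignment", class(m))
  }
  m
}

check_stop_codons <- function(m) {
  n_codon <- ncol(m) / 3
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(n_codon)) {
      cod <- paste(m[i, (3 * j - 2):(3 * j)], collapse = "")
      if (cod %in% STOP_CODONS && j < n_codon) {
        stop("internal stop codon ", cod, " in sequence ",
             rownames(m)[i], " at codon ", j)
      }
    }
  }
  invisible(TRUE)
}

#' Write an alignment to FASTA
#'
#' @param alignment character matrix with sequence-id rownames.
#' @param path output path.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(c(paste0(">", rownames(alignment)[i]),
                 paste(alignment[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Map alignment columns to reference-sequence residue positions
#'
#' Builds the 1-based, strictly increasing correspondence between alignment
#' columns and residue positions of a named reference sequence; columns where
#' the reference carries a gap are flagged unmapped. All region and site
#' coordinates reported by the divergence and selection scans use this map.
#'
#' @param alignment an alignment matrix (see [read_alignment()]).
#' @param reference_id row name of the reference sequence.
#' @return a data.frame (class `ref_coord_map`) with columns `column`,
#'   `ref_pos` (NA where unmapped) and `mapped`; attribute `reference_id`.
#' @export
map_to_reference <- function(alignment, reference_id) {
  if (!reference_id %in% rownames(alignment)) {
    stop("reference id not in alignment: ", reference_id)
  }
  ref <- alignment[reference_id, ]
  is_res <- !(ref %in% GAP_CHARS)
  ref_pos <- rep(NA_integer_, length(ref))
  ref_pos[is_res] <- seq_len(sum(is_res))
  out <- data.frame(column = seq_along(ref), ref_pos = ref_pos,
                    mapped = is_res)
  attr(out, "reference_id") <- reference_id
  class(out) <- c("ref_coord_map", class(out))
  out
}

#' Read or write a gene family count table
#'
#' Tab-separated table with a `family_id` column followed by one integer
#' column per species; counts must be non-negative integers.
#'
#' @param path TSV path.
#' @return data.frame of class `family_count_table`.
#' @export
read_family_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_family_count_table(df)
}

#' @rdname read_family_counts
#' @param df data.frame with `family_id` plus species count columns.
#' @export
as_family_count_table <- function(df) {
  if (!"family_id" %in% names(df)) stop("missing 'family_id' column")
  sp <- setdiff(names(df), "family_id")
  if (!length(sp)) stop("no species columns")
  for (s in sp) {
    v <- df[[s]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      stop("counts for species ", s, " must be non-negative integers")
    }
    df[[s]] <- as.integer(v)
  }
  class(df) <- unique(c("family_count_table", class(df)))
  df
}

#' @rdname read_family_counts
#' @param table a `family_count_table`.
#' @export
write_family_counts <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

count_matrix <- function(table, species = NULL) {
  sp <- setdiff(names(table), "family_id")
  m <- as.matrix(table[, sp, drop = FALSE])
  rownames(m) <- table$family_id
  if (!is.null(species)) {
    missing <- setdiff(species, colnames(m))
    if (length(missing)) stop("species missing from count table: ",
                              paste(missing, collapse = ", "))
    m <- m[, species, drop = FALSE]
  }
  m
}
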