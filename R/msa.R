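#' @useDynLib defold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif setNames sd var
#' @importFrom utils head read.table write.table
NULL

# 21-letter alphabet: 20 amino acids + gap, gap encoded last (q = 21)
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
GAP_STATE <- 21L

#' Construct an aligned-sequence object
#'
#' An `msa` holds equal-length aligned rows over the 20 amino acids plus the
#' gap character `-`, the row index of the query sequence, and a map from
#' current columns back to the original alignment columns (updated by the
#' trimming operations so positions always trace back to the query numbering).
#'
#' @param sequences character vector of aligned rows (equal length).
#' @param ids optional sequence identifiers.
#' @param query_index row index of the query (default 1).
#' @param column_map integer vector of original column indices; defaults to
#'   `1:nchar`.
#' @return an object of class `msa` with fields `aln` (character matrix),
#'   `ids`, `query_index`, `column_map`, `n_rows`, `n_cols`.
#' @export
new_msa <- function(sequences, ids = NULL, query_index = 1L, column_map = NULL) {
  if (length(sequences) < 1L) stop("input error: alignment has no sequences")
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("format error: aligned rows have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")")
  n_cols <- widths[[1L]]
  if (n_cols < 1L) stop("input error: zero-width alignment")
  aln <- matrix(unlist(strsplit(toupper(sequences), "", fixed = TRUE)),
                nrow = length(sequences), ncol = n_cols, byrow = TRUE)
  # non-standard letters (X, B, Z, ., *) are treated as gaps
  aln[!(aln %in% AA_ALPHABET)] <- "-"
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (is.null(column_map)) column_map <- seq_len(n_cols)
  stopifnot(length(column_map) == n_cols, !is.unsorted(column_map, strictly = TRUE))
  structure(list(aln = aln, ids = as.character(ids),
                 query_index = as.integer(query_index),
                 column_map = as.integer(column_map),
                 n_rows = nrow(aln), n_cols = n_cols),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", x$n_rows, " rows x ", x$n_cols,
      " columns\n", sep = "")
  cat("  query row:", x$query_index, "(", x$ids[x$query_index], ")\n")
  cat("  query:", paste(x$aln[x$query_index, seq_len(min(60, x$n_cols))],
                        collapse = ""),
      if (x$n_cols > 60) "...\n" else "\n")
  invisible(x)
}

#' Alignment rows as strings
#' @param msa an `msa` object.
#' @return character vector of aligned rows.
#' @export
msa_sequences <- function(msa) {
  apply(msa$aln, 1L, paste, collapse = "")
}

#' Integer-encoded alignment (A..Y = 1..20, gap = 21)
#' @param msa an `msa` object.
#' @return integer matrix `n_rows x n_cols`.
#' @export
msa_encode <- function(msa) {
  m <- match(msa$aln, AA_ALPHABET)
  dim(m) <- dim(msa$aln)
  storage.mode(m) <- "integer"
  m
}

#' Read a multiple sequence alignment
#'
#' FASTA and Stockholm files are parsed with Biostrings; A3M files are
#' normalized by deleting lowercase insert states (columns not aligned to the
#' query) before validation, so all rows align to query columns.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"a3m"`, `"stockholm"`. Default guesses
#'   from the file extension, falling back to FASTA.
#' @param query_index row of the query sequence (default 1).
#' @return an `msa` object.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m", "stockholm"),
                     query_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, a3m = "a3m", sto = "stockholm", stk = "stockholm",
                     stockholm = "stockholm", "fasta")
  }
  if (format == "stockholm") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(aln)
    ids <- names(seqs)
  } else {
    recs <- read_fasta_records(path)
    ids <- recs$ids
    seqs <- recs$seqs
    if (format == "a3m") {
      # lowercase letters are insertions relative to the query columns; '.'
      # is the matching gap placeholder -- both are removed
      seqs <- gsub("[a-z.]", "", seqs)
    }
  }
  if (length(seqs) == 0L) stop("input error: empty alignment file: ", path)
  new_msa(seqs, ids = ids, query_index = query_index)
}

# Minimal FASTA record reader used for FASTA and A3M (A3M rows are not valid
# equal-width FASTA until insert states are stripped, so Biostrings'
# alignment reader cannot be applied before normalization).
read_fasta_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("input error: empty alignment file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[[1L]]) stop("format error: file does not start with a '>' header")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  if (length(seqs) != length(ids))
    stop("format error: header without sequence body")
  list(ids = ids, seqs = unname(seqs))
}

#' Write an alignment to FASTA
#' @param msa an `msa` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  seqs <- msa_sequences(msa)
  writeLines(paste0(">", msa$ids, "\n", seqs), path)
  invisible(path)
}

#' Remove gap-rich alignment columns
#'
#' A column is dropped when its gap count strictly exceeds
#' `max_gap_fraction` of the number of rows; a column with exactly the
#' threshold fraction of gaps is kept. Surviving original column indices are
#' recorded in `column_map`.
#'
#' @param msa an `msa` object.
#' @param max_gap_fraction maximum tolerated gap fraction, in (0, 1).
#' @return trimmed `msa`.
#' @export
filter_columns <- function(msa, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction < 1)
  gap_counts <- colSums(msa$aln == "-")
  keep <- gap_counts <= max_gap_fraction * msa$n_rows
  if (!any(keep)) stop("degenerate alignment: all columns exceed the gap threshold")
  out <- msa
  out$aln <- msa$aln[, keep, drop = FALSE]
  out$column_map <- msa$column_map[keep]
  out$n_cols <- sum(keep)
  out
}

#' Remove gap-rich sequences
#'
#' Non-query rows whose gap fraction, measured over the query's non-gap
#' columns, strictly exceeds `max_gap_fraction` are deleted; a row at
#' exactly the threshold is kept. The query row is always retained.
#'
#' @param msa an `msa` object.
#' @param max_gap_fraction maximum tolerated per-row gap fraction.
#' @return filtered `msa`.
#' @export
filter_sequences <- function(msa, max_gap_fraction = 0.3) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction < 1)
  qcols <- which(msa$aln[msa$query_index, ] != "-")
  if (length(qcols) == 0L) qcols <- seq_len(msa$n_cols)
  gap_frac <- rowMeans(msa$aln[, qcols, drop = FALSE] == "-")
  keep <- gap_frac <= max_gap_fraction
  keep[msa$query_index] <- TRUE
  out <- msa
  out$aln <- msa$aln[keep, , drop = FALSE]
  out$ids <- msa$ids[keep]
  out$query_index <- sum(keep[seq_len(msa$query_index)])
  out$n_rows <- sum(keep)
  if (out$n_rows < 2L)
    warning("insufficient alignment depth: fewer than 2 sequences remain")
  out
}

#' Identity-based sequence weights
#'
#' Down-weights redundant sequences: the weight of a row is the reciprocal of
#' the number of rows (itself included) whose fractional identity to it is at
#' least `identity_threshold`. The effective depth `m_eff` is the sum of the
#' weights. Set `identity_threshold = NULL` to disable reweighting (all
#' weights 1).
#'
#' @param msa an `msa` object (typically trimmed).
#' @param identity_threshold identity fraction in (0, 1], or `NULL` for off.
#' @return an object of class `seq_weights`: list with `weights`, `m_eff`,
#'   `identity_threshold`.
#' @export
compute_weights <- function(msa, identity_threshold = 0.8) {
  n <- msa$n_rows
  if (is.null(identity_threshold)) {
    w <- rep(1, n)
    return(structure(list(weights = w, m_eff = n, identity_threshold = NULL),
                     class = "seq_weights"))
  }
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  enc <- msa_encode(msa)
  # identity counts via per-state indicator cross-products
  counts <- matrix(0, n, n)
  for (s in sort(unique(as.vector(enc)))) {
    ind <- enc == s
    counts <- counts + tcrossprod(ind * 1)
  }
  neighbors <- rowSums(counts / msa$n_cols >= identity_threshold)
  w <- 1 / neighbors
  structure(list(weights = w, m_eff = sum(w),
                 identity_threshold = identity_threshold),
            class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat("Sequence weights for", length(x$weights), "rows; m_eff =",
      format(x$m_eff, digits = 5),
      if (is.null(x$identity_threshold)) "(reweighting off)\n"
      else paste0("(identity threshold ", x$identity_threshold, ")\n"))
  invisible(x)
}

#' Write a trimming report
#'
#' Two TSV sections: per original column, whether it survived column
#' filtering; per input sequence, its gap fraction and retention.
#'
#' @param original the alignment before trimming.
#' @param trimmed the alignment after trimming.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(original, trimmed, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns", con)
  col_kept <- original$column_map %in% trimmed$column_map
  write.table(data.frame(column = original$column_map, kept = col_kept),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# sequences", con)
  gf <- rowMeans(original$aln == "-")
  write.table(data.frame(id = original$ids, gap_fraction = round(gf, 4),
                         kept = original$ids %in% trimmed$ids),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
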