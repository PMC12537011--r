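# Multiple sequence alignments: parsing, identity filtering, and per-position
# conservation scores.

#' Construct an MSA object
#'
#' A reference row plus aligned homolog rows over the alphabet of the 20
#' amino acids, `-` (gap) and `X`. All rows share one width W; ungapping the
#' reference row recovers the reference protein sequence.
#'
#' @param reference_id Identifier of the reference protein.
#' @param reference_row Aligned reference string.
#' @param query_rows Named character vector of aligned homolog rows.
#' @param insertions_removed Logical flag recording whether lowercase
#'   insertion characters were stripped at parse time (A3M input).
#' @return An object of class `msa`.
#' @export
msa <- function(reference_id, reference_row, query_rows,
                insertions_removed = FALSE) {
  reference_row <- toupper(reference_row)
  query_rows <- vapply(query_rows, toupper, character(1))
  W <- nchar(reference_row)
  bad <- which(nchar(query_rows) != W)
  if (length(bad))
    stop("alignment row '", names(query_rows)[bad[1]] %||% bad[1],
         "' has width ", nchar(query_rows)[bad[1]], ", expected ", W)
  structure(list(reference_id = reference_id, reference_row = reference_row,
                 query_rows = query_rows,
                 insertions_removed = insertions_removed),
            class = "msa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ref ", x$reference_id, ": ", length(x$query_rows),
      " queries x ", nchar(x$reference_row), " columns\n", sep = "")
  invisible(x)
}

#' Ungapped reference sequence of an MSA
#' @param x An `msa`.
#' @return The reference protein sequence (gaps removed).
#' @export
msa_reference_sequence <- function(x) gsub("-", "", x$reference_row, fixed = TRUE)

#' Parse a multiple sequence alignment
#'
#' Supported dialects:
#' * `a3m` — FASTA-like; lowercase letters are insertions relative to the
#'   reference profile and are removed (together with `.` insertion gaps),
#'   after which every row aligns to reference columns.
#' * `aligned_fasta` — FASTA with rows ingested verbatim; `.` gaps are
#'   normalized to `-`.
#' * `clustal` — CLUSTAL blocks concatenated per sequence id; the header
#'   line and conservation rulers are skipped.
#'
#' The reference row is the first record unless `reference_id` names one.
#'
#' @param path Alignment file.
#' @param dialect One of `"a3m"`, `"clustal"`, `"aligned_fasta"`.
#' @param reference_id Optional id of the reference record.
#' @return An `msa`.
#' @export
parse_alignment <- function(path, dialect = c("a3m", "clustal",
                                              "aligned_fasta"),
                            reference_id = NULL) {
  dialect <- match.arg(dialect)
  rows <- switch(dialect,
    a3m = parse_fasta_rows(path, strip_insertions = TRUE),
    aligned_fasta = parse_fasta_rows(path, strip_insertions = FALSE),
    clustal = parse_clustal_rows(path))
  rows[] <- gsub(".", "-", rows, fixed = TRUE)
  if (length(rows) < 1L) stop("alignment ", path, " contains no sequences")
  ref_idx <- if (is.null(reference_id)) 1L else match(reference_id, names(rows))
  if (is.na(ref_idx)) stop("reference '", reference_id, "' not in alignment")
  W <- nchar(rows[[ref_idx]])
  bad <- which(nchar(rows) != W)
  if (length(bad))
    stop("ragged alignment ", path, ": row '", names(rows)[bad[1]],
         "' has width ", nchar(rows[[bad[1]]]), ", expected ", W)
  msa(names(rows)[ref_idx], rows[[ref_idx]], rows[-ref_idx],
      insertions_removed = (dialect == "a3m"))
}

parse_fasta_rows <- function(path, strip_insertions) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA-style alignment: ", path)
  id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  if (strip_insertions) seqs <- gsub("[a-z.]", "", seqs)
  names(seqs) <- id
  seqs
}

parse_clustal_rows <- function(path) {
  lines <- readLines(path)
  if (length(lines) && grepl("^CLUSTAL", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  out <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next                     # conservation ruler line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.~-]+)\\s*\\d*\\s*$", ln))[[1]]
    if (length(m) != 3L) next
    out[[m[2]]] <- paste0(out[[m[2]]] %||% "", m[3])
  }
  if (!length(out)) stop("no sequence rows found in CLUSTAL file ", path)
  vapply(out, identity, character(1))
}

#' Percent identity of a query row to the reference row
#'
#' Matches are positions where the query residue equals the reference
#' residue (case-insensitive; a gap never matches a gap, and `X` never
#' matches). The denominator is the *full aligned reference length* W —
#' residues in folded and disordered regions as well as gap columns — so
#' fragmentary homologs score low.
#'
#' @param reference_row,query_row Equal-length aligned strings.
#' @return Identity in \[0, 1\].
#' @export
percent_identity <- function(reference_row, query_row) {
  if (nchar(reference_row) != nchar(query_row))
    stop("rows differ in length (", nchar(reference_row), " vs ",
         nchar(query_row), ")")
  r <- strsplit(toupper(reference_row), "")[[1]]
  q <- strsplit(toupper(query_row), "")[[1]]
  match_ok <- r == q & r != "-" & r != "X"
  sum(match_ok) / length(r)
}

#' Drop weakly related homologs from an MSA
#'
#' Retains query rows with identity to the reference strictly greater than
#' `min_identity`; rows at or below the cutoff (default 0.20, i.e. "<= 20%
#' identity") are removed. The reference is always retained.
#'
#' @param x An `msa`.
#' @param min_identity Identity at or below which a query is dropped.
#' @return The filtered `msa`.
#' @export
filter_homologs <- function(x, min_identity = 0.20) {
  stopifnot(inherits(x, "msa"))
  idents <- vapply(x$query_rows, percent_identity,
                   reference_row = x$reference_row, FUN.VALUE = numeric(1))
  x$query_rows <- x$query_rows[idents > min_identity]
  x
}

#' Per-position conservation scores from an MSA
#'
#' For each reference (non-gap) column i, counts over the *query rows only*:
#' `support` = number of queries with a residue (non-gap) there, and matches
#' = number of query residues equal to the reference residue
#' (case-insensitive; `X` never matches). The conservation score is
#' matches / support, `NA` where support is 0. The track is indexed in
#' reference ungapped coordinates.
#'
#' @param x An `msa` (typically after [filter_homologs()]).
#' @return Data.frame with `pos`, `ref_aa`, `cs`, `support`.
#' @export
conservation_scores <- function(x) {
  stopifnot(inherits(x, "msa"))
  ref <- strsplit(x$reference_row, "")[[1]]
  ref_cols <- which(ref != "-")
  n_q <- length(x$query_rows)
  if (n_q > 0L) {
    qmat <- do.call(rbind, strsplit(unname(x$query_rows), ""))
    qmat <- qmat[, ref_cols, drop = FALSE]
    refv <- matrix(ref[ref_cols], nrow = n_q, ncol = length(ref_cols),
                   byrow = TRUE)
    non_gap <- qmat != "-"
    match_ref <- non_gap & qmat == refv & qmat != "X"
    support <- colSums(non_gap)
    matches <- colSums(match_ref)
  } else {
    support <- matches <- rep(0L, length(ref_cols))
  }
  cs <- ifelse(support > 0, matches / support, NA_real_)
  data.frame(pos = seq_along(ref_cols), ref_aa = ref[ref_cols], cs = cs,
             support = as.integer(support), stringsAsFactors = FALSE)
}

#' Write a conservation track as TSV
#'
#' @param track Output of [conservation_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
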