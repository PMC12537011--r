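# Labeled intervals on proteins (IDRs, phase-separation segments, motifs)
# and IDR functional-role classification.

#' Construct a set of labeled protein segments
#'
#' Intervals are stored 1-based inclusive (the natural residue-numbering
#' convention in R and in published region descriptions such as
#' "residues 75-85"); the BED writer converts to 0-based half-open on
#' output. Overlapping or abutting intervals sharing one label are merged,
#' and intervals are sorted.
#'
#' @param protein_id Identifier (recycled).
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param label Segment label per interval: `"idr"`, `"ps_segment"` or
#'   `"motif"` (recycled).
#' @return A data.frame of class `segment_set` with columns `protein_id`,
#'   `start`, `end`, `label`.
#' @export
#' @examples
#' segment_set("P1", c(3, 10), c(7, 14), "idr")
segment_set <- function(protein_id = character(), start = integer(),
                        end = integer(), label = character()) {
  n <- length(start)
  stopifnot(length(end) == n)
  if (n > 0) {
    protein_id <- rep_len(protein_id, n)
    label <- rep_len(label, n)
  } else {
    protein_id <- character(); label <- character()
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start))
    stop("segments need 1 <= start <= end")
  df <- data.frame(protein_id = protein_id, start = start, end = end,
                   label = label, stringsAsFactors = FALSE)
  df <- normalize_segments(df)
  class(df) <- c("segment_set", "data.frame")
  df
}

# Merge overlapping/abutting intervals within (protein_id, label) and sort.
normalize_segments <- function(df) {
  if (nrow(df) == 0L) return(df)
  parts <- split(df, list(df$protein_id, df$label), drop = TRUE)
  merged <- lapply(parts, function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(protein_id = d$protein_id[1],
               start = IRanges::start(ir), end = IRanges::end(ir),
               label = d$label[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$protein_id, out$label, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

segment_widths <- function(segments) segments$end - segments$start + 1L

# Residue positions covered by a segment set (one protein).
segment_positions <- function(segments) {
  if (nrow(segments) == 0L) return(integer())
  sort(unique(unlist(Map(seq.int, segments$start, segments$end))))
}

#' Classify one IDR by its overlap with phase-separation segments
#'
#' For each experimentally annotated phase-separation (PS) segment the
#' overlap fraction is the shared residue count divided by the *PS-segment*
#' length; the IDR's fraction is the maximum over segments. Role:
#' *driving* when the IDR covers more than 50% of a PS segment,
#' *participating* when the overlap is positive but at most 50% (an exact
#' 50% overlap is participating), *non_participating* when there is none.
#'
#' @param idr Length-2 numeric `(start, end)` or a one-row `segment_set`,
#'   1-based inclusive.
#' @param ps_segments A `segment_set` of PS segments on the same protein
#'   (may be empty).
#' @param driving_cut Overlap fraction strictly above which the IDR is
#'   driving; default 0.5.
#' @return A list with `start`, `end`, `role`, `overlap_fraction`.
#' @export
classify_idr_role <- function(idr, ps_segments, driving_cut = 0.5) {
  if (is.data.frame(idr)) {
    stopifnot(nrow(idr) == 1L)
    s <- idr$start; e <- idr$end
  } else {
    s <- idr[1]; e <- idr[2]
  }
  stopifnot(s >= 1, e >= s)
  frac <- 0
  if (!is.null(ps_segments) && nrow(ps_segments) > 0L) {
    ov <- pmax(0L, pmin(e, ps_segments$end) - pmax(s, ps_segments$start) + 1L)
    frac <- max(ov / segment_widths(ps_segments))
  }
  role <- if (frac > driving_cut) "driving"
          else if (frac > 0) "participating"
          else "non_participating"
  list(start = as.integer(s), end = as.integer(e), role = role,
       overlap_fraction = frac)
}

#' Classify every IDR of a protein
#'
#' @param idrs A `segment_set` of IDRs.
#' @param ps_segments A `segment_set` of PS segments on the same protein.
#' @param driving_cut Passed to [classify_idr_role()].
#' @return Data.frame: `protein_id`, `start`, `end`, `role`,
#'   `overlap_fraction`.
#' @export
classify_idr_roles <- function(idrs, ps_segments, driving_cut = 0.5) {
  if (nrow(idrs) == 0L)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), role = character(),
                      overlap_fraction = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(idrs)), function(i) {
    r <- classify_idr_role(c(idrs$start[i], idrs$end[i]), ps_segments,
                           driving_cut)
    data.frame(protein_id = idrs$protein_id[i], start = r$start, end = r$end,
               role = r$role, overlap_fraction = r$overlap_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Greedy redundancy filter on sequence identity
#'
#' Walks proteins in order of sorted identifier and drops any whose global
#' pairwise identity to an already-retained protein exceeds `max_identity`
#' (default 0.50). Identity is alignment matches divided by the longer
#' sequence's length, from a Needleman-Wunsch global alignment
#' (BLOSUM62, gap open 10, extension 0.5).
#'
#' @param sequences Named character vector of protein sequences.
#' @param max_identity Identity strictly above which a pair is redundant.
#' @return Names of the retained proteins, in processing order.
#' @export
redundancy_filter <- function(sequences, max_identity = 0.50) {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  ids <- sort(names(sequences))
  kept <- character()
  for (id in ids) {
    red <- FALSE
    for (k in kept) {
      if (pairwise_identity(sequences[[id]], sequences[[k]]) > max_identity) {
        red <- TRUE
        break
      }
    }
    if (!red) kept <- c(kept, id)
  }
  kept
}

#' Global-alignment sequence identity of two sequences
#'
#' @param a,b Amino-acid sequence strings.
#' @return Matches / length of the longer sequence, in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / max(nchar(a), nchar(b))
}

#' Keep proteins whose IDRs touch a phase-separation segment
#'
#' Retains entries with at least one residue of overlap between any IDR and
#' any PS segment.
#'
#' @param idr_sets Named list of `segment_set` IDRs per protein.
#' @param ps_sets Named list of `segment_set` PS segments per protein
#'   (missing or empty entries count as no overlap).
#' @return Names of the retained proteins.
#' @export
ps_overlap_filter <- function(idr_sets, ps_sets) {
  stopifnot(!is.null(names(idr_sets)))
  keep <- vapply(names(idr_sets), function(id) {
    idr <- idr_sets[[id]]
    ps <- ps_sets[[id]]
    if (is.null(ps) || nrow(ps) == 0L || nrow(idr) == 0L) return(FALSE)
    ov <- IRanges::findOverlaps(IRanges::IRanges(idr$start, idr$end),
                                IRanges::IRanges(ps$start, ps$end))
    length(ov) > 0L
  }, logical(1))
  names(idr_sets)[keep]
}

#' Probability that conserved disordered residues sit in PS-contributing IDRs
#'
#' "PS-contributing" is the union of driving and participating IDRs (those
#' with any PS-segment overlap). Among the protein's conserved disordered
#' residues (pLDDT <= `plddt_cut`, score <= `conserved_cut`), returns the
#' fraction located inside that union; `NA` when the protein has no
#' conserved disordered residues.
#'
#' @param profile A scored `residue_profile` with pLDDT.
#' @param ps_segments A `segment_set` of PS segments.
#' @param conserved_cut Score threshold for "conserved" (inclusive).
#' @param plddt_cut Disorder threshold (inclusive).
#' @return A probability in \[0, 1\], or `NA`.
#' @export
conserved_in_ps_probability <- function(profile, ps_segments,
                                        conserved_cut = 0.5, plddt_cut = 70) {
  stopifnot(inherits(profile, "residue_profile"))
  if (is.null(profile$score) || is.null(profile$plddt))
    stop("profile must be scored and carry pLDDT")
  idrs <- extract_idrs(profile, plddt_cut = plddt_cut)
  roles <- classify_idr_roles(idrs, ps_segments)
  contrib <- roles[roles$role %in% c("driving", "participating"), ,
                   drop = FALSE]
  in_contrib <- rep(FALSE, profile_length(profile))
  if (nrow(contrib) > 0L)
    in_contrib[unlist(Map(seq.int, contrib$start, contrib$end))] <- TRUE
  conserved_dis <- !is.na(profile$score) & profile$score <= conserved_cut &
    profile$plddt <= plddt_cut
  denom <- sum(conserved_dis)
  if (denom == 0L) return(NA_real_)
  sum(conserved_dis & in_contrib) / denom
}

# ---- segment I/O -----------------------------------------------------------

#' Write segments as BED
#'
#' BED uses 0-based half-open coordinates; the internal 1-based inclusive
#' `(start, end)` becomes `(start - 1, end)`.
#'
#' @param segments A `segment_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$protein_id,
                    chromStart = segments$start - 1L,
                    chromEnd = segments$end,
                    name = segments$label)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read segments from BED
#'
#' @param path BED file (columns chrom, chromStart, chromEnd and optionally
#'   name, used as the label).
#' @return A `segment_set` in 1-based inclusive coordinates.
#' @export
read_segments_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  label <- if (ncol(bed) >= 4) bed[[4]] else "ps_segment"
  segment_set(bed[[1]], bed[[2]] + 1L, bed[[3]], label)
}

#' Write a human-readable segment report
#'
#' TSV in 1-based inclusive coordinates matching published residue
#' numbering (e.g. "residues 75-85").
#'
#' @param segments A `segment_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_report <- function(segments, path) {
  utils::write.table(as.data.frame(segments), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
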