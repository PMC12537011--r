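# Conserved low-score motif detection: bidirectional greedy scan,
# residue-level intersection, proximity merging, length filter.

#' One-directional greedy candidate scan
#'
#' Implements one pass of the motif search over a score track. Scanning from
#' the chosen terminus: find the first residue i with score at or below
#' `threshold`; extend the segment residue by residue toward the opposite
#' terminus while the running average stays at or below `threshold` (an
#' average of exactly `threshold` does not end the segment); the first
#' residue j whose inclusion pushes the average above `threshold` closes the
#' candidate as (i .. j-1), and scanning resumes from j. A segment that
#' reaches the terminus without breaching is kept whole. The backward
#' direction is the exact mirror image.
#'
#' @param scores Numeric score track (finite values; `NA` treated as
#'   non-admissible and breaks any running segment).
#' @param threshold Admissibility threshold on the running average
#'   (inclusive), default 0.5.
#' @param direction `"forward"` (from the N-terminus) or `"backward"`.
#' @return Sorted integer vector of candidate residue indices (1-based).
#' @export
scan_direction <- function(scores, threshold = 0.5,
                           direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  n <- length(scores)
  if (n == 0L) return(integer())
  s <- if (direction == "backward") rev(scores) else scores
  idx <- integer()
  i <- 1L
  while (i <= n) {
    if (is.na(s[i]) || s[i] > threshold) {
      i <- i + 1L
      next
    }
    # start a candidate at i; extend while the running mean stays admissible
    total <- 0
    j <- i
    while (j <= n && !is.na(s[j]) && (total + s[j]) / (j - i + 1L) <= threshold) {
      total <- total + s[j]
      j <- j + 1L
    }
    idx <- c(idx, i:(j - 1L))
    # resume scanning from the breaching residue j (j can only breach if its
    # own score exceeds threshold, so no candidate restarts at j itself)
    i <- j
  }
  if (direction == "backward") idx <- sort(n + 1L - idx)
  idx
}

# contiguous runs of a sorted integer index set -> data.frame(start, end)
runs_from_indices <- function(idx) {
  if (length(idx) == 0L)
    return(data.frame(start = integer(), end = integer()))
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  data.frame(start = idx[brk[-length(brk)] + 1L], end = idx[brk[-1L]])
}

#' Find conserved low-score motifs in a score track
#'
#' The full motif-identification procedure:
#' 1. run [scan_direction()] from both termini;
#' 2. intersect the two candidate residue-index sets (trimming terminal
#'    residues that are admissible in only one direction);
#' 3. re-extract maximal contiguous runs from the intersection;
#' 4. drop runs whose mean score exceeds `threshold` (possible after
#'    intersection);
#' 5. merge nearby runs: when one run starts within `merge_gap` intervening
#'    residues of another's end and the spanning segment (including the
#'    intervening residues) has mean score strictly below `threshold`, the
#'    two are replaced by the span. Among several eligible adjacent pairs
#'    the one with the smallest spanning mean is merged first (ties: smaller
#'    gap, then leftmost), repeating until no pair qualifies — a canonical
#'    order that makes the result independent of scan direction;
#' 6. drop motifs shorter than `min_len`.
#'
#' @param scores Numeric score track for the region searched (an IDR or a
#'   whole protein).
#' @param threshold Average-score admissibility threshold, default 0.5.
#' @param merge_gap Maximum number of intervening residues bridged by the
#'   merge rule, default 8.
#' @param min_len Minimum reported motif length, default 4.
#' @return Data.frame with one row per motif: `start`, `end` (1-based
#'   inclusive, local to `scores`), `length`, `mean_score`.
#' @export
find_motifs <- function(scores, threshold = 0.5, merge_gap = 8L,
                        min_len = 4L) {
  fwd <- scan_direction(scores, threshold, "forward")
  bwd <- scan_direction(scores, threshold, "backward")
  runs <- runs_from_indices(intersect(fwd, bwd))
  if (nrow(runs) > 0L) {
    means <- vapply(seq_len(nrow(runs)), function(k)
      mean(scores[runs$start[k]:runs$end[k]]), numeric(1))
    runs <- runs[means <= threshold, , drop = FALSE]
  }
  # proximity merge, best (lowest spanning mean) eligible pair first
  repeat {
    if (nrow(runs) < 2L) break
    k_all <- seq_len(nrow(runs) - 1L)
    gaps <- runs$start[k_all + 1L] - runs$end[k_all] - 1L
    span_means <- vapply(k_all, function(k) {
      span <- scores[runs$start[k]:runs$end[k + 1L]]
      if (anyNA(span)) NA_real_ else mean(span)
    }, numeric(1))
    eligible <- which(gaps <= merge_gap & !is.na(span_means) &
                        span_means < threshold)
    if (!length(eligible)) break
    best <- eligible[order(span_means[eligible], gaps[eligible],
                           eligible)][1L]
    runs$end[best] <- runs$end[best + 1L]
    runs <- runs[-(best + 1L), , drop = FALSE]
  }
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  rownames(runs) <- NULL
  data.frame(
    start = runs$start, end = runs$end,
    length = runs$end - runs$start + 1L,
    mean_score = vapply(seq_len(nrow(runs)), function(k)
      mean(scores[runs$start[k]:runs$end[k]]), numeric(1)))
}

#' Find motifs across a protein's IDRs
#'
#' Runs [find_motifs()] independently inside each IDR of a profile (the
#' default scope; set `whole_protein = TRUE` to scan the full score track)
#' and reports motifs in protein coordinates with their subsequences.
#'
#' @param profile A scored `residue_profile`.
#' @param idrs A `segment_set` of IDRs; defaults to [extract_idrs()] when
#'   pLDDT is present.
#' @param whole_protein Scan the full track instead of per-IDR.
#' @param threshold,merge_gap,min_len Passed to [find_motifs()].
#' @return A data.frame: `protein_id`, `start`, `end` (1-based inclusive),
#'   `length`, `sequence`, `mean_score`.
#' @export
find_profile_motifs <- function(profile, idrs = NULL, whole_protein = FALSE,
                                threshold = 0.5, merge_gap = 8L,
                                min_len = 4L) {
  stopifnot(inherits(profile, "residue_profile"))
  if (is.null(profile$score)) stop("profile is not scored")
  regions <- if (whole_protein) {
    data.frame(start = 1L, end = profile_length(profile))
  } else {
    if (is.null(idrs)) idrs <- extract_idrs(profile)
    idrs
  }
  res <- profile_residues(profile)
  out <- lapply(seq_len(nrow(regions)), function(k) {
    a <- regions$start[k]; b <- regions$end[k]
    m <- find_motifs(profile$score[a:b], threshold, merge_gap, min_len)
    if (nrow(m) == 0L) return(NULL)
    data.frame(protein_id = profile$protein_id,
               start = m$start + a - 1L, end = m$end + a - 1L,
               length = m$length,
               sequence = vapply(seq_len(nrow(m)), function(j)
                 paste(res[(m$start[j] + a - 1L):(m$end[j] + a - 1L)],
                       collapse = ""), character(1)),
               mean_score = m$mean_score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      sequence = character(), mean_score = numeric(),
                      stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Fraction of conserved residues located inside motifs, per amino acid
#'
#' For each amino-acid type, among the profile's conserved residues (score
#' strictly below `conserved_cut`), the fraction lying inside any motif.
#' `NA` for types with no conserved residues.
#'
#' @param profile A scored `residue_profile`.
#' @param motifs Motif table in protein coordinates (`start`, `end`), e.g.
#'   from [find_profile_motifs()].
#' @param conserved_cut Score strictly below which a residue counts as
#'   conserved, default 0.5.
#' @return Named numeric vector over [aa_alphabet()].
#' @export
fraction_conserved_in_motifs <- function(profile, motifs,
                                         conserved_cut = 0.5) {
  stopifnot(inherits(profile, "residue_profile"))
  if (is.null(profile$score)) stop("profile is not scored")
  res <- profile_residues(profile)
  in_motif <- rep(FALSE, length(res))
  if (nrow(motifs) > 0L)
    in_motif[unlist(Map(seq.int, motifs$start, motifs$end))] <- TRUE
  conserved <- !is.na(profile$score) & profile$score < conserved_cut
  vapply(stats::setNames(aa_alphabet(), aa_alphabet()), function(a) {
    denom <- sum(conserved & res == a)
    if (denom == 0L) NA_real_ else sum(conserved & in_motif & res == a) / denom
  }, numeric(1))
}

#' Write motifs as CSV
#'
#' Columns `protein_id`, `start`, `end` (1-based inclusive), `length`,
#' `sequence`, `mean_score`.
#'
#' @param motifs Motif table from [find_profile_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_csv <- function(motifs, path) {
  utils::write.csv(motifs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write motifs as BED
#' @param motifs Motif table with `protein_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_bed <- function(motifs, path) {
  seg <- segment_set(motifs$protein_id, motifs$start, motifs$end, "motif")
  write_segments_bed(seg, path)
}
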