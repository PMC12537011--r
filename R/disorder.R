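# Residue-level order/disorder and tolerance classification from pLDDT and
# entropy scores.

#' Classify residues by structural order and mutational tolerance
#'
#' A residue is *disordered* when its pLDDT is at or below `plddt_cut`
#' (default 70), otherwise *ordered*. Independently it is *conserved* when
#' its tolerance score is at or below `conserved_cut` (default 0.5),
#' *flexible* when at or above `flexible_cut` (default 2.0), *intermediate*
#' between the two, and *missing* for nonstandard residues without a score.
#'
#' @param profile A scored `residue_profile` with `plddt` present.
#' @param plddt_cut Disorder threshold on pLDDT (inclusive on the disordered
#'   side).
#' @param conserved_cut Upper score bound for the conserved class (inclusive).
#' @param flexible_cut Lower score bound for the flexible class (inclusive).
#' @param stratum_edges Interior bin edges for [plddt_strata()].
#' @return A data.frame with one row per residue: `pos`, `aa`, `plddt`,
#'   `score`, `order_state`, `tolerance_state`, `plddt_stratum`.
#' @export
classify_residues <- function(profile, plddt_cut = 70, conserved_cut = 0.5,
                              flexible_cut = 2.0,
                              stratum_edges = c(50, 70, 90)) {
  stopifnot(inherits(profile, "residue_profile"))
  if (flexible_cut <= conserved_cut)
    stop("flexible_cut (", flexible_cut, ") must exceed conserved_cut (",
         conserved_cut, ")")
  if (is.null(profile$plddt)) stop("profile has no pLDDT track")
  if (is.null(profile$score)) stop("profile is not scored; run score_profile()")
  plddt <- profile$plddt
  score <- profile$score
  order_state <- ifelse(plddt <= plddt_cut, "disordered", "ordered")
  tolerance_state <- ifelse(
    is.na(score), "missing",
    ifelse(score <= conserved_cut, "conserved",
           ifelse(score >= flexible_cut, "flexible", "intermediate")))
  data.frame(
    pos = seq_along(plddt),
    aa = profile_residues(profile),
    plddt = plddt,
    score = score,
    order_state = order_state,
    tolerance_state = tolerance_state,
    plddt_stratum = plddt_strata(plddt, edges = stratum_edges),
    stringsAsFactors = FALSE)
}

#' Assign pLDDT confidence strata
#'
#' Four left-closed bins over \[0, 100\]; with the default edges 50/70/90
#' the strata are \[0,50), \[50,70), \[70,90), \[90,100\]. The edges are
#' configurable because published analyses rarely print them; note that with
#' left-closed bins a residue at exactly pLDDT 70 falls in stratum 3 even
#' though the order/disorder rule (<= 70) calls it disordered.
#'
#' @param plddt Numeric vector in \[0, 100\].
#' @param edges Three increasing interior edges.
#' @return Integer vector of strata 1..4.
#' @export
plddt_strata <- function(plddt, edges = c(50, 70, 90)) {
  stopifnot(length(edges) == 3L, !is.unsorted(edges, strictly = TRUE))
  if (any(plddt < 0 | plddt > 100, na.rm = TRUE))
    stop("pLDDT values must lie in [0, 100]")
  findInterval(plddt, edges) + 1L
}

#' Extract intrinsically disordered regions
#'
#' Maximal runs of consecutive residues with pLDDT at or below `plddt_cut`,
#' kept when at least `min_len` residues long.
#'
#' @param profile A `residue_profile` with `plddt`.
#' @param plddt_cut Disorder threshold (inclusive).
#' @param min_len Minimum run length to report.
#' @return A `segment_set` data.frame with label `"idr"` (1-based inclusive
#'   coordinates; see [segment_set()]).
#' @export
extract_idrs <- function(profile, plddt_cut = 70, min_len = 1L) {
  stopifnot(inherits(profile, "residue_profile"))
  if (is.null(profile$plddt)) stop("profile has no pLDDT track")
  dis <- profile$plddt <= plddt_cut
  r <- rle(dis)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  segment_set(profile$protein_id, starts[keep], ends[keep], label = "idr")
}

#' Keep proteins with a minimum disordered fraction
#'
#' Retains profiles whose fraction of disordered residues (pLDDT <=
#' `plddt_cut`), computed over canonical residues, is at least `min_frac`.
#'
#' @param profiles List of `residue_profile` objects with pLDDT.
#' @param min_frac Minimum disordered fraction (inclusive), default 0.10.
#' @param plddt_cut Disorder threshold.
#' @return The retained sublist, names preserved.
#' @export
disordered_fraction_filter <- function(profiles, min_frac = 0.10,
                                       plddt_cut = 70) {
  keep <- vapply(profiles, function(p) {
    if (is.null(p$plddt)) stop("profile '", p$protein_id, "' has no pLDDT")
    canon <- is_canonical_aa(profile_residues(p))
    frac <- sum(p$plddt[canon] <= plddt_cut) / sum(canon)
    frac >= min_frac
  }, logical(1))
  profiles[keep]
}
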