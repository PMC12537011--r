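# Aggregate analyses: group comparisons, per-amino-acid correlation,
# LLR aggregation and clustering, density surfaces.

#' Two-sided Mann-Whitney U comparison of two score groups
#'
#' Wraps the rank-sum test with the conventions used throughout the
#' analysis: two-sided, exact enumeration for small tie-free samples (both
#' groups at most 20 observations), normal approximation with tie correction
#' otherwise, and a significance label with the standard cutpoints
#' (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05, dagger p < 0.10,
#' `n.s.` p >= 0.10).
#'
#' @param scores_a,scores_b Numeric vectors, each non-empty.
#' @param name_a,name_b Group names carried into the result.
#' @return A list with `group_a_name`, `group_b_name`, `n_a`, `n_b`,
#'   `u_statistic` (U of group a), `p_value`, `significance_label`.
#' @export
group_compare <- function(scores_a, scores_b, name_a = "a", name_b = "b") {
  if (length(scores_a) < 1L || length(scores_b) < 1L)
    stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(scores_a, scores_b)) > 0L
  use_exact <- !has_ties && length(scores_a) <= 20L && length(scores_b) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(
    scores_a, scores_b, alternative = "two.sided",
    exact = use_exact, correct = !use_exact))
  # zero-variance pooled data (all values tied) has no rank signal at all
  p <- if (is.na(wt$p.value)) 1 else min(wt$p.value, 1)
  list(group_a_name = name_a, group_b_name = name_b,
       n_a = length(scores_a), n_b = length(scores_b),
       u_statistic = unname(wt$statistic),
       p_value = p,
       significance_label = significance_label(p))
}

#' Significance label for a p-value
#'
#' @param p A p-value.
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05),
#'   `"†"` (p < 0.10, marginal) or `"n.s."`.
#' @export
significance_label <- function(p) {
  if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else if (p < 0.10) "†"
  else "n.s."
}

#' Correlation of mean tolerance and mean conservation per amino acid
#'
#' Within each pLDDT stratum, computes the mean tolerance score and mean
#' conservation score of every amino-acid type, then the Pearson
#' correlation over those per-type means. Methionine is excluded by default
#' (its frequent position as initiator residue makes its mutational-effect
#' predictions unreliable). Types absent from a stratum are dropped and the
#' remaining count reported.
#'
#' @param profiles List of scored `residue_profile`s with pLDDT.
#' @param conservation_tracks Named list (by protein id) of
#'   [conservation_scores()] tables.
#' @param stratum_edges Interior pLDDT bin edges, see [plddt_strata()].
#' @param exclude Amino acids excluded from the correlation, default `"M"`.
#' @return Data.frame with one row per stratum: `stratum`, `r`, `n_aa`, and
#'   the per-type means as a nested `means` list-column is omitted for
#'   simplicity; use [aa_stratum_means()] for the underlying table.
#' @export
aa_correlation <- function(profiles, conservation_tracks,
                           stratum_edges = c(50, 70, 90), exclude = "M") {
  means <- aa_stratum_means(profiles, conservation_tracks, stratum_edges)
  means <- means[!(means$aa %in% exclude), , drop = FALSE]
  out <- lapply(sort(unique(means$stratum)), function(st) {
    d <- means[means$stratum == st & !is.na(means$mean_score) &
                 !is.na(means$mean_cs), , drop = FALSE]
    r <- if (nrow(d) >= 3L &&
             stats::sd(d$mean_score) > 0 && stats::sd(d$mean_cs) > 0) {
      stats::cor(d$mean_score, d$mean_cs)
    } else {
      warning("stratum ", st, ": too few amino-acid types for a correlation")
      NA_real_
    }
    data.frame(stratum = st, r = r, n_aa = nrow(d))
  })
  do.call(rbind, out)
}

#' Per-amino-acid mean score and conservation by pLDDT stratum
#'
#' @inheritParams aa_correlation
#' @return Data.frame `stratum`, `aa`, `mean_score`, `mean_cs`, `n`.
#' @export
aa_stratum_means <- function(profiles, conservation_tracks,
                             stratum_edges = c(50, 70, 90)) {
  rows <- lapply(profiles, function(p) {
    if (is.null(p$score) || is.null(p$plddt))
      stop("profile '", p$protein_id, "' must be scored and carry pLDDT")
    track <- conservation_tracks[[p$protein_id]]
    cs <- if (is.null(track)) rep(NA_real_, profile_length(p)) else track$cs
    data.frame(aa = profile_residues(p),
               stratum = plddt_strata(p$plddt, stratum_edges),
               score = p$score, cs = cs, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d <- d[is_canonical_aa(d$aa) & !is.na(d$score), , drop = FALSE]
  agg <- do.call(rbind, lapply(split(d, list(d$stratum, d$aa), drop = TRUE),
    function(g) data.frame(
      stratum = g$stratum[1], aa = g$aa[1],
      mean_score = mean(g$score),
      mean_cs = if (all(is.na(g$cs))) NA_real_ else mean(g$cs, na.rm = TRUE),
      n = nrow(g), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$stratum, agg$aa), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Mean LLR vector per wild-type amino acid
#'
#' Averages the 20-entry LLR vectors of all (masked) residues of each
#' wild-type amino-acid type into a 20 x 20 matrix (rows wild-type, columns
#' mutant). The diagonal is 0 whenever inputs obey the wild-type-zero
#' invariant; rows of types absent from the mask are `NA`.
#'
#' @param profiles List of `residue_profile`s with LLR matrices.
#' @param region_masks Optional named list (by protein id) of logical
#'   vectors selecting residues (e.g. driving-IDR residues); default all.
#' @return 20 x 20 numeric matrix with dimnames from [aa_alphabet()].
#' @export
mean_llr_by_aa <- function(profiles, region_masks = NULL) {
  aa <- aa_alphabet()
  acc <- matrix(0, 20L, 20L, dimnames = list(aa, aa))
  cnt <- stats::setNames(integer(20L), aa)
  for (p in profiles) {
    if (is.null(p$llr)) stop("profile '", p$protein_id, "' has no LLR matrix")
    mask <- if (is.null(region_masks)) rep(TRUE, profile_length(p))
            else region_masks[[p$protein_id]]
    res <- profile_residues(p)
    for (i in which(mask & is_canonical_aa(res) &
                      !apply(is.na(p$llr), 1L, any))) {
      acc[res[i], ] <- acc[res[i], ] + p$llr[i, ]
      cnt[res[i]] <- cnt[res[i]] + 1L
    }
  }
  out <- acc / cnt
  out[cnt == 0L, ] <- NA_real_
  out
}

#' Deterministic 2-D embedding by principal components
#'
#' Projects the 20 per-amino-acid LLR vectors onto their first two
#' principal directions. Serves as the default deterministic embedder for
#' [embed_and_cluster()]; any function mapping a 20 x 20 matrix to a
#' 20 x 2 matrix (for example a UMAP wrapper) can be plugged in instead.
#'
#' @param m A complete numeric matrix (rows = amino acids).
#' @return A 20 x 2 matrix of coordinates.
#' @export
embed_pca <- function(m) {
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  out <- matrix(0, nrow(m), 2L, dimnames = list(rownames(m), c("dim1", "dim2")))
  out[, seq_len(k)] <- pc$x[, seq_len(k)]
  out
}

#' Embed amino-acid LLR vectors and cluster them
#'
#' Embeds the 20 x 20 mean-LLR matrix into two dimensions with a pluggable
#' embedder (default [embed_pca()]) and groups the amino acids by
#' agglomerative hierarchical clustering (average linkage, Euclidean
#' distance) cut at `n_clusters`. Deterministic given a deterministic
#' embedder.
#'
#' @param mean_llr Complete 20 x 20 matrix from [mean_llr_by_aa()].
#' @param embedder Function matrix -> n x 2 coordinates.
#' @param n_clusters Number of clusters, default 5.
#' @return A list with `embedding` (20 x 2) and `cluster` (named integer
#'   vector of labels).
#' @export
embed_and_cluster <- function(mean_llr, embedder = embed_pca,
                              n_clusters = 5L) {
  if (anyNA(mean_llr))
    stop("mean_llr has missing rows; exclude or impute those amino acids")
  emb <- embedder(mean_llr)
  stopifnot(is.matrix(emb), nrow(emb) == nrow(mean_llr), ncol(emb) == 2L)
  d <- stats::dist(emb, method = "euclidean")
  if (max(d) == 0) {
    cl <- stats::setNames(rep(1L, nrow(emb)), rownames(mean_llr))
    return(list(embedding = emb, cluster = cl))
  }
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = n_clusters)
  names(cl) <- rownames(mean_llr)
  list(embedding = emb, cluster = cl)
}

#' Negative-log density surface of two observables
#'
#' Equal-width 2-D histogram over the observed range, normalized so the
#' density integrates to 1, returned as -log(P). Empty bins are `NA`
#' (masked) rather than infinite. The conventional contour levels at
#' 0.5-unit spacing over the occupied range are attached as attribute
#' `"levels"`.
#'
#' @param x,y Paired finite observations (at least 2 points).
#' @param bins Number of bins per axis, default 100.
#' @return List with `x_breaks`, `y_breaks`, `neg_log_p` (bins x bins
#'   matrix, x rows).
#' @export
density_surface <- function(x, y, bins = 100L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 finite paired observations")
  xb <- seq(min(x), max(x), length.out = bins + 1L)
  yb <- seq(min(y), max(y), length.out = bins + 1L)
  # degenerate axes (all values identical) get a token unit width
  if (xb[1] == xb[length(xb)]) xb <- xb[1] + seq(-0.5, 0.5, length.out = bins + 1L)
  if (yb[1] == yb[length(yb)]) yb <- yb[1] + seq(-0.5, 0.5, length.out = bins + 1L)
  xi <- pmin(pmax(findInterval(x, xb, rightmost.closed = TRUE), 1L), bins)
  yi <- pmin(pmax(findInterval(y, yb, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1
  bin_area <- diff(xb)[1] * diff(yb)[1]
  dens <- counts / (length(x) * bin_area)
  nlp <- ifelse(dens > 0, -log(dens), NA_real_)
  lv <- range(nlp, na.rm = TRUE)
  attr(nlp, "levels") <- seq(floor(lv[1] / 0.5) * 0.5, lv[2], by = 0.5)
  list(x_breaks = xb, y_breaks = yb, neg_log_p = nlp)
}

#' Write a density surface as a gridded TSV
#'
#' @param surface Output of [density_surface()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(surface, path) {
  bins <- nrow(surface$neg_log_p)
  xc <- (surface$x_breaks[-1] + surface$x_breaks[-(bins + 1L)]) / 2
  yc <- (surface$y_breaks[-1] + surface$y_breaks[-(bins + 1L)]) / 2
  grid <- expand.grid(xi = seq_len(bins), yi = seq_len(bins))
  out <- data.frame(x = xc[grid$xi], y = yc[grid$yi],
                    neg_log_p = surface$neg_log_p[cbind(grid$xi, grid$yi)])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
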