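# End-to-end analysis pipeline: score -> classify -> conserve -> regions ->
# motifs -> stats, with a resolved-config record and deterministic outputs.

#' Default pipeline configuration
#'
#' All thresholds of the analysis with their standard defaults: disorder at
#' pLDDT <= 70, conserved at score <= 0.5, flexible at score >= 2.0,
#' homolog identity filter at 20%, driving overlap above 50%, motif merge
#' gap 8 residues, minimum motif length 4, redundancy cutoff 50% identity,
#' minimum disordered fraction 10%.
#'
#' @param ... Named overrides of any default.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    plddt_cut = 70, conserved_cut = 0.5, flexible_cut = 2.0,
    identity_min = 0.20, overlap_driving = 0.5,
    merge_gap = 8L, motif_min_len = 4L,
    redundancy_max = 0.50, disordered_frac_min = 0.10,
    stratum_edges = c(50, 70, 90),
    seed = 1L, out_dir = "idrtol_run")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

validate_config <- function(cfg) {
  if (cfg$flexible_cut <= cfg$conserved_cut)
    stop("config error: flexible_cut must exceed conserved_cut")
  if (cfg$identity_min < 0 || cfg$identity_min > 1 ||
      cfg$redundancy_max < 0 || cfg$redundancy_max > 1)
    stop("config error: identity thresholds must lie in [0, 1]")
  invisible(cfg)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Consumes a dataset laid out as written by [make_dataset()] (a
#' `manifest.tsv` naming per-protein LLR/pLDDT/MSA files, plus
#' `segments.bed` with PS segments) and executes every stage: residue
#' scoring, order/tolerance classification, conservation scoring with the
#' identity filter, IDR extraction and role classification, motif
#' detection within IDRs, and the aggregate statistics (per-amino-acid
#' correlations, role-group comparisons, mean-LLR matrix, density
#' surface). Each stage's tables are written under `cfg$out_dir` together
#' with the resolved configuration; rerunning with an identical config and
#' dataset is byte-identical.
#'
#' @param data_dir Dataset directory.
#' @param cfg Configuration from [default_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(data_dir, cfg = default_config()) {
  validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(data_dir, "manifest.tsv")
  if (!file.exists(manifest_path))
    stop("stage input: manifest.tsv not found in ", data_dir)
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  segs <- read_segments_bed(file.path(data_dir, "segments.bed"))
  ps_all <- segs[segs$label == "ps_segment", , drop = FALSE]

  log_lines <- c(paste("idrtol", as.character(utils::packageVersion("idrtol"))),
                 paste("seed", cfg$seed),
                 paste("proteins", nrow(manifest)))
  set.seed(cfg$seed)

  profiles <- list()
  tracks <- list()
  class_rows <- list()
  role_rows <- list()
  motif_rows <- list()
  for (k in seq_len(nrow(manifest))) {
    id <- manifest$protein_id[k]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("stage '", what, "' failed on ", id, ": ", conditionMessage(e)))
    }
    prof <- stage("score", {
      p <- read_llr_table(file.path(data_dir, manifest$llr[k]), id)
      p$plddt <- read_plddt_table(file.path(data_dir, manifest$plddt[k]))
      score_profile(p)
    })
    profiles[[id]] <- prof
    cls <- stage("classify",
                 classify_residues(prof, cfg$plddt_cut, cfg$conserved_cut,
                                   cfg$flexible_cut, cfg$stratum_edges))
    class_rows[[id]] <- cbind(protein_id = id, cls)
    tracks[[id]] <- stage("conserve", {
      m <- parse_alignment(file.path(data_dir, manifest$msa[k]), "a3m")
      conservation_scores(filter_homologs(m, cfg$identity_min))
    })
    idrs <- extract_idrs(prof, cfg$plddt_cut)
    ps <- ps_all[ps_all$protein_id == id, , drop = FALSE]
    roles <- stage("regions",
                   classify_idr_roles(idrs, ps, cfg$overlap_driving))
    role_rows[[id]] <- roles
    motif_rows[[id]] <- stage("motifs",
      find_profile_motifs(prof, idrs, threshold = cfg$conserved_cut,
                          merge_gap = cfg$merge_gap,
                          min_len = cfg$motif_min_len))
  }

  classes <- do.call(rbind, class_rows)
  roles <- do.call(rbind, role_rows)
  motifs <- do.call(rbind, motif_rows)
  rownames(classes) <- rownames(roles) <- rownames(motifs) <- NULL

  # aggregate statistics
  idr_scores <- function(role_name) {
    sel <- roles[roles$role == role_name, , drop = FALSE]
    unlist(lapply(seq_len(nrow(sel)), function(j) {
      p <- profiles[[sel$protein_id[j]]]
      p$score[sel$start[j]:sel$end[j]]
    }))
  }
  comparisons <- list()
  for (pair in list(c("driving", "participating"),
                    c("driving", "non_participating"),
                    c("participating", "non_participating"))) {
    a <- idr_scores(pair[1]); b <- idr_scores(pair[2])
    if (length(a) && length(b))
      comparisons[[paste(pair, collapse = "_vs_")]] <-
        as.data.frame(group_compare(a, b, pair[1], pair[2]))
  }
  comparisons <- do.call(rbind, comparisons)
  corr <- aa_correlation(profiles, tracks, cfg$stratum_edges)
  mllr <- mean_llr_by_aa(profiles)
  all_plddt <- unlist(lapply(profiles, `[[`, "plddt"))
  all_score <- unlist(lapply(profiles, `[[`, "score"))
  surf <- density_surface(all_plddt, all_score, bins = 50L)

  # reports
  utils::write.table(classes, file.path(out, "residue_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(roles, file.path(out, "idr_roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_motif_csv(motifs, file.path(out, "motifs.csv"))
  for (id in names(tracks))
    write_conservation_tsv(tracks[[id]],
                           file.path(out, paste0(id, "_conservation.tsv")))
  if (!is.null(comparisons))
    utils::write.table(comparisons, file.path(out, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(corr, file.path(out, "aa_correlation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(round(mllr, 6), file.path(out, "mean_llr.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  write_density_tsv(surf, file.path(out, "density_surface.tsv"))
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  writeLines(log_lines, file.path(out, "run.log"))

  invisible(list(profiles = profiles, classes = classes, tracks = tracks,
                 roles = roles, motifs = motifs, comparisons = comparisons,
                 aa_correlation = corr, mean_llr = mllr, density = surf,
                 config = cfg))
}
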