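# Seeded synthetic datasets with the statistical structure the analysis
# assumes: bimodal score populations by structural class, conserved
# low-score motifs planted in flexible IDRs, MSAs whose conservation tracks
# anticorrelate with the score, and driver IDRs shifted toward low scores.
#
# Randomness convention: generator functions draw from R's current RNG
# stream; the entry points that take a `synthetic_spec` seed it once via
# `set.seed(spec$seed)`, so a fixed spec reproduces byte-identical data.

#' Parameters of the synthetic dataset generator
#'
#' Defaults encode the structure the analysis is designed to detect:
#' folded blocks are mutationally constrained (target score mean 0.3,
#' sd 0.15) with high structural confidence (pLDDT mean 90, sd 5);
#' flexible disordered blocks are tolerant (score mean 2.4, sd 0.3) with
#' low confidence (pLDDT mean 50, sd 10); planted motifs inside IDRs are
#' constrained (score mean 0.25, sd 0.1) but keep disordered pLDDT.
#' Conservation is coupled to the score through the per-position match
#' probability `q_i = clamp(1 - score_i/log(20) + eps, 0, 1)` with
#' `eps ~ N(0, 0.05)`. Driver proteins have their IDR scores shifted down
#' by `delta_driving` relative to non-participating controls and carry a
#' phase-separation segment mostly covered by the motif-bearing IDR.
#'
#' @param seed Integer seed.
#' @param n_proteins Number of proteins per role when building a dataset.
#' @param block_lengths Named list of length ranges per block kind.
#' @param score_model Named list of `(mean, sd)` per block kind; scores are
#'   truncated to (0.01, log(20) - 0.01).
#' @param plddt_model Named list of `(mean, sd)` for folded and disordered
#'   residues; pLDDT truncated to \[0, 100\].
#' @param cs_noise_sd Sd of the conservation-coupling noise `eps`.
#' @param n_queries Homolog rows per synthetic MSA.
#' @param gap_rate Per-column gap probability in homolog rows.
#' @param insertion_rate Per-column probability of a lowercase insertion in
#'   A3M output.
#' @param delta_driving Downward score shift of driver-protein IDRs.
#' @param llr_jitter Relative heterogeneity of non-wild-type LLR entries.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_proteins = 8L,
                           block_lengths = list(folded = c(40L, 80L),
                                                flexible_idr = c(30L, 60L),
                                                conserved_motif = c(6L, 14L)),
                           score_model = list(folded = c(0.30, 0.15),
                                              flexible_idr = c(2.40, 0.30),
                                              conserved_motif = c(0.25, 0.10)),
                           plddt_model = list(folded = c(90, 5),
                                              disordered = c(50, 10)),
                           cs_noise_sd = 0.05, n_queries = 200L,
                           gap_rate = 0.10, insertion_rate = 0.02,
                           delta_driving = 0.5, llr_jitter = 0.25) {
  stopifnot(all(vapply(block_lengths, function(b) all(b > 0), logical(1))))
  structure(as.list(environment()), class = "synthetic_spec")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Build an LLR vector with a prescribed tolerance score
#'
#' Inverts the entropy score: returns a 20-vector with the wild-type entry
#' exactly 0 whose [esm2_score()] is within 1e-6 of `target_score`. The
#' non-wild-type entries are `-c * w_k` with fixed positive weights `w_k`
#' (optionally jittered from the current RNG stream for heterogeneity) and
#' the concentration `c >= 0` solved by bisection on the entropy, which
#' decreases continuously from `log(20)` (c = 0) towards 0.
#'
#' @param target_score Desired score, strictly inside (0, log(20)).
#' @param wt_index Wild-type column index in 1..20.
#' @param jitter Relative weight heterogeneity in \[0, 1); 0 gives the
#'   symmetric construction.
#' @return Numeric 20-vector.
#' @export
make_llr_for_score <- function(target_score, wt_index, jitter = 0) {
  if (!is.finite(target_score) || target_score <= 0 ||
      target_score >= log(20L))
    stop("target_score must lie strictly inside (0, log(20))")
  stopifnot(wt_index >= 1L, wt_index <= 20L)
  w <- 1 + jitter * stats::runif(19L)
  entropy_at <- function(cc) {
    v <- numeric(20L)
    v[-wt_index] <- -cc * w
    esm2_score(v)
  }
  lo <- 0; hi <- 1
  while (entropy_at(hi) > target_score) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (entropy_at(mid) > target_score) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  cc <- (lo + hi) / 2
  v <- numeric(20L)
  v[-wt_index] <- -cc * w
  v
}

#' Generate one synthetic protein
#'
#' Concatenates a block layout (default folded / flexible IDR containing a
#' planted conserved motif / folded for drivers and clients; no motif for
#' the `non_mlo` role), draws per-residue target scores and pLDDT from the
#' spec's per-kind models, builds LLR rows via [make_llr_for_score()], and
#' emits ground-truth segments. Driver proteins carry a PS segment covered
#' mostly (>50%) by the motif-bearing IDR; clients carry one whose IDR
#' overlap is at most 50%; `non_mlo` proteins carry none. Draws from the
#' current RNG stream — seed the session (or use [make_dataset()]) for
#' reproducibility.
#'
#' @param spec A `synthetic_spec`.
#' @param protein_id Identifier.
#' @param role `"driver"`, `"client"` or `"non_mlo"`.
#' @param layout Optional explicit character vector of block kinds.
#' @return List with `profile` (scored `residue_profile`), `truth` (a
#'   `segment_set` of true IDRs, motifs and PS segments) and `role`.
#' @export
make_protein <- function(spec, protein_id = "synth1",
                         role = c("driver", "client", "non_mlo"),
                         layout = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  role <- match.arg(role)
  if (is.null(layout)) {
    layout <- if (role == "non_mlo") {
      c("folded", "flexible_idr", "folded")
    } else {
      c("folded", "flexible_idr", "conserved_motif", "flexible_idr", "folded")
    }
  }
  draw_len <- function(kind) {
    rng <- spec$block_lengths[[kind]]
    sample(rng[1]:rng[2], 1L)
  }
  lens <- vapply(layout, draw_len, integer(1))
  kinds <- rep(layout, lens)
  L <- length(kinds)
  # Per-residue target scores; driver flexible-IDR blocks are shifted down
  # by delta_driving relative to the control model (motif blocks are already
  # near the constrained floor).
  target <- numeric(L)
  plddt <- numeric(L)
  eps <- log(20L) / 1000
  for (kind in unique(kinds)) {
    idx <- which(kinds == kind)
    sm <- spec$score_model[[kind]]
    shift <- if (role == "driver" && kind == "flexible_idr")
      spec$delta_driving else 0
    target[idx] <- rtrunc_norm(length(idx), sm[1] - shift, sm[2],
                               eps, log(20L) - eps)
    pm <- spec$plddt_model[[if (kind == "folded") "folded" else "disordered"]]
    plddt[idx] <- rtrunc_norm(length(idx), pm[1], pm[2], 0, 100)
  }
  wt_idx <- sample.int(20L, L, replace = TRUE)
  sequence <- paste(aa_alphabet()[wt_idx], collapse = "")
  llr <- t(vapply(seq_len(L), function(i)
    make_llr_for_score(target[i], wt_idx[i], jitter = spec$llr_jitter),
    numeric(20L)))
  profile <- score_profile(residue_profile(protein_id, sequence,
                                           plddt = plddt, llr = llr))
  # ground truth segments
  block_end <- cumsum(lens)
  block_start <- block_end - lens + 1L
  is_dis <- layout != "folded"
  truth <- list()
  if (any(is_dis)) {
    # merge adjacent disordered blocks into true IDR intervals
    r <- rle(is_dis)
    be <- cumsum(r$lengths); bs <- be - r$lengths + 1L
    keep <- which(r$values)
    truth$idr <- segment_set(protein_id, block_start[bs[keep]],
                             block_end[be[keep]], "idr")
  } else truth$idr <- segment_set()
  motif_blocks <- which(layout == "conserved_motif")
  truth$motif <- if (length(motif_blocks)) {
    segment_set(protein_id, block_start[motif_blocks],
                block_end[motif_blocks], "motif")
  } else segment_set()
  truth$ps <- segment_set()
  if (role == "driver" && length(motif_blocks)) {
    # PS segment inside the motif-bearing IDR: IDR covers 100% of it
    mb <- motif_blocks[1]
    ps_start <- max(1L, block_start[mb] - 5L)
    ps_end <- min(L, block_end[mb] + 5L)
    truth$ps <- segment_set(protein_id, ps_start, ps_end, "ps_segment")
  } else if (role == "client" && length(motif_blocks)) {
    # PS segment mostly outside the IDR: overlap fraction <= 0.5
    mb <- motif_blocks[1]
    idr_end <- block_end[be_last_disordered(layout, block_end)]
    ov <- 5L
    ps_start <- idr_end - ov + 1L
    ps_end <- min(L, idr_end + ov + 10L)
    truth$ps <- segment_set(protein_id, ps_start, ps_end, "ps_segment")
  }
  list(profile = profile, truth = truth, role = role)
}

be_last_disordered <- function(layout, block_end) {
  max(which(layout != "folded"))
}

#' Generate a synthetic MSA coupled to a profile's scores
#'
#' Per-position match probability
#' `q_i = clamp(1 - score_i / log(20) + eps_i, 0, 1)`, `eps_i ~ N(0,
#' cs_noise_sd)`: constrained positions are conserved, tolerant positions
#' diverge, so the conservation track anticorrelates with the score.
#' Each homolog row matches the reference with probability `q_i`, otherwise
#' substitutes a random different residue; gaps appear at `gap_rate`.
#' Draws from the current RNG stream.
#'
#' @param reference_profile A scored `residue_profile`.
#' @param n_queries Number of homolog rows.
#' @param gap_rate Per-column gap probability.
#' @param cs_noise_sd Sd of the coupling noise.
#' @param q Optional explicit vector of match probabilities overriding the
#'   coupling.
#' @return An `msa`; the realized `q` is attached as attribute `"q"`.
#' @export
make_msa <- function(reference_profile, n_queries = 200L, gap_rate = 0.10,
                     cs_noise_sd = 0.05, q = NULL) {
  stopifnot(inherits(reference_profile, "residue_profile"))
  ref <- profile_residues(reference_profile)
  L <- length(ref)
  if (is.null(q)) {
    score <- reference_profile$score
    if (is.null(score)) stop("reference profile is not scored")
    q <- pmin(pmax(1 - score / log(20L) + stats::rnorm(L, 0, cs_noise_sd),
                   0), 1)
  }
  stopifnot(length(q) == L)
  aa <- aa_alphabet()
  rows <- vapply(seq_len(n_queries), function(k) {
    gap <- stats::runif(L) < gap_rate
    match <- stats::runif(L) < q
    out <- ref
    for (i in which(!match)) out[i] <- sample(setdiff(aa, ref[i]), 1L)
    out[gap] <- "-"
    paste(out, collapse = "")
  }, character(1))
  names(rows) <- sprintf("homolog%03d", seq_len(n_queries))
  m <- msa(reference_profile$protein_id, paste(ref, collapse = ""), rows)
  attr(m, "q") <- q
  m
}

#' Write an MSA in A3M format
#'
#' Optionally plants lowercase insertion runs (invisible to reference
#' coordinates) in homolog rows at `insertion_rate` per column, exercising
#' the A3M normalization path of [parse_alignment()].
#'
#' @param x An `msa`.
#' @param path Output path.
#' @param insertion_rate Per-column insertion probability.
#' @return `path`, invisibly.
#' @export
write_msa_a3m <- function(x, path, insertion_rate = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0(">", x$reference_id), x$reference_row), con)
  aa_low <- tolower(aa_alphabet())
  for (nm in names(x$query_rows)) {
    row <- x$query_rows[[nm]]
    if (insertion_rate > 0) {
      ch <- strsplit(row, "")[[1]]
      ins <- stats::runif(length(ch)) < insertion_rate
      ch[ins] <- paste0(ch[ins], sample(aa_low, sum(ins), replace = TRUE))
      row <- paste(ch, collapse = "")
    }
    writeLines(c(paste0(">", nm), row), con)
  }
  invisible(path)
}

#' Write an MSA as aligned FASTA
#' @param x An `msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(x, path) {
  lines <- c(rbind(paste0(">", c(x$reference_id, names(x$query_rows))),
                   c(x$reference_row, unname(x$query_rows))))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete labeled synthetic dataset on disk
#'
#' Seeds the RNG from `spec$seed`, generates `n_proteins` proteins per role
#' (driver / client / non_mlo), and writes every module's input format:
#' FASTA sequences, per-protein LLR and pLDDT TSVs, A3M alignments,
#' segment BED files (truth IDRs, motifs, PS segments) and a manifest TSV.
#' Rerunning with the same spec reproduces identical files.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (`protein_id`, `role`, `length`,
#'   `n_true_motifs`, plus file paths), invisibly the same as written.
#' @export
make_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  roles <- rep(c("driver", "client", "non_mlo"), each = spec$n_proteins)
  ids <- sprintf("SYN%03d", seq_along(roles))
  fasta <- file.path(dir, "proteins.fasta")
  unlink(fasta)
  rows <- list()
  all_segments <- list()
  for (k in seq_along(ids)) {
    pr <- make_protein(spec, ids[k], roles[k])
    prof <- pr$profile
    llr_path <- file.path(dir, paste0(ids[k], "_llr.tsv"))
    plddt_path <- file.path(dir, paste0(ids[k], "_plddt.tsv"))
    msa_path <- file.path(dir, paste0(ids[k], ".a3m"))
    write_llr_table(prof, llr_path)
    utils::write.table(
      data.frame(pos = seq_len(profile_length(prof)), plddt = prof$plddt),
      plddt_path, sep = "\t", quote = FALSE, row.names = FALSE)
    m <- make_msa(prof, n_queries = spec$n_queries,
                  gap_rate = spec$gap_rate, cs_noise_sd = spec$cs_noise_sd)
    write_msa_a3m(m, msa_path, insertion_rate = spec$insertion_rate)
    cat(">", ids[k], "\n", prof$sequence, "\n", sep = "",
        file = fasta, append = TRUE)
    all_segments[[k]] <- rbind(as.data.frame(pr$truth$idr),
                               as.data.frame(pr$truth$motif),
                               as.data.frame(pr$truth$ps))
    rows[[k]] <- data.frame(
      protein_id = ids[k], role = roles[k],
      length = profile_length(prof),
      n_true_motifs = nrow(pr$truth$motif),
      llr = basename(llr_path), plddt = basename(plddt_path),
      msa = basename(msa_path), stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, all_segments)
  class(seg) <- c("segment_set", "data.frame")
  write_segments_bed(seg, file.path(dir, "segments.bed"))
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
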