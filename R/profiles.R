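# Per-protein residue profiles: sequence, pLDDT track, LLR matrix, tolerance
# scores.

#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order. This is the
#' canonical column order of every LLR matrix in the package.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Maximum attainable tolerance score
#'
#' Upper bound of the entropy score: `log(20)`, reached when all 20 LLR
#' entries are equal (uniform mutation preference).
#'
#' @return `log(20)`, about 2.9957.
#' @export
max_score <- function() log(20L)

is_canonical_aa <- function(x) x %in% aa_alphabet()

#' Construct a residue profile
#'
#' Bundles a protein's sequence with its per-residue pLDDT confidence track
#' and its L x 20 log-likelihood-ratio (LLR) matrix. Columns of `llr` follow
#' [aa_alphabet()]; row i holds the LLRs of mutating residue i to each of the
#' 20 amino acids, with the wild-type entry 0 by definition (the log ratio of
#' the wild-type against itself). Positions with nonstandard residues
#' (X, U, B, Z, ...) are kept in the coordinate system but their LLR row and
#' score are `NA` and they are excluded from all aggregations.
#'
#' @param protein_id Identifier string.
#' @param sequence Amino-acid string (one-letter codes), length L.
#' @param plddt Optional numeric vector length L, values in \[0, 100\].
#' @param llr Optional numeric L x 20 matrix in canonical column order.
#' @param score Optional numeric vector length L (usually derived via
#'   [score_profile()]).
#' @return An object of class `residue_profile`.
#' @export
#' @examples
#' p <- residue_profile("toy", "ACD", llr = matrix(0, 3, 20))
#' p <- score_profile(p)
#' p$score  # all log(20): uniform LLRs carry no preference
residue_profile <- function(protein_id, sequence, plddt = NULL, llr = NULL,
                            score = NULL) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(seq_chars)
  if (!is.null(plddt)) {
    if (length(plddt) != L)
      stop("plddt length ", length(plddt), " != sequence length ", L)
    if (any(plddt < 0 | plddt > 100, na.rm = TRUE))
      stop("pLDDT values must lie in [0, 100]")
  }
  if (!is.null(llr)) {
    llr <- as.matrix(llr)
    if (nrow(llr) != L)
      stop("llr has ", nrow(llr), " rows but sequence length is ", L)
    if (ncol(llr) != 20L)
      stop("llr must have 20 columns in canonical amino-acid order")
    colnames(llr) <- aa_alphabet()
    # wild-type-vs-itself LLR is identically zero; enforce for canonical rows
    canon <- is_canonical_aa(seq_chars)
    wt_col <- match(seq_chars, aa_alphabet())
    for (i in which(canon)) {
      if (is.finite(llr[i, wt_col[i]]) && abs(llr[i, wt_col[i]]) > 1e-9)
        stop("wild-type LLR must be 0 at position ", i,
             " (found ", llr[i, wt_col[i]], ")")
      llr[i, wt_col[i]] <- 0
    }
    llr[!canon, ] <- NA_real_
  }
  if (!is.null(score) && length(score) != L)
    stop("score length ", length(score), " != sequence length ", L)
  structure(
    list(protein_id = protein_id, sequence = paste(seq_chars, collapse = ""),
         plddt = plddt, llr = llr, score = score),
    class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  L <- nchar(x$sequence)
  cat("<residue_profile> ", x$protein_id, ": ", L, " residues",
      if (!is.null(x$plddt)) "; pLDDT" else "",
      if (!is.null(x$llr)) "; LLR" else "",
      if (!is.null(x$score)) "; scored" else "",
      "\n", sep = "")
  invisible(x)
}

profile_length <- function(profile) nchar(profile$sequence)

profile_residues <- function(profile) strsplit(profile$sequence, "")[[1]]

#' Entropy-based mutational tolerance score of one residue
#'
#' Converts a 20-element LLR vector into a single tolerance value: the
#' Shannon entropy (natural log) of the softmax of the vector,
#' \deqn{-\sum_i p_i \log p_i, \quad p_i = e^{LLR_i} / \sum_j e^{LLR_j}.}
#' A uniform vector gives the maximum `log(20)` (every mutation equally
#' acceptable — full tolerance); a vector dominated by one entry approaches 0
#' (one residue strongly preferred — strong constraint). The score is
#' invariant to adding a constant to the whole vector and to permuting it.
#'
#' @param llr_vector Numeric vector of exactly 20 finite values.
#' @return A single number in \[0, log(20)\].
#' @export
#' @examples
#' esm2_score(rep(0, 20))          # log(20)
#' esm2_score(c(50, rep(0, 19)))   # ~0: one amino acid dominates
esm2_score <- function(llr_vector) {
  if (length(llr_vector) != 20L)
    stop("llr_vector must have exactly 20 entries, got ", length(llr_vector))
  if (!is.numeric(llr_vector) || any(!is.finite(llr_vector)))
    stop("llr_vector entries must all be finite numbers")
  # log-sum-exp stabilised softmax entropy
  u <- llr_vector - max(llr_vector)
  w <- exp(u)
  s <- sum(w)
  p <- w / s
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  min(max(h, 0), log(20L))
}

#' Score every residue of a profile
#'
#' Applies [esm2_score()] to each row of the profile's LLR matrix.
#' Rows of nonstandard residues yield `NA`. Idempotent.
#'
#' @param profile A `residue_profile` with an `llr` matrix.
#' @return The profile with its `score` vector populated.
#' @export
score_profile <- function(profile) {
  stopifnot(inherits(profile, "residue_profile"))
  if (is.null(profile$llr))
    stop("profile '", profile$protein_id, "' has no LLR matrix to score")
  scores <- apply(profile$llr, 1L, function(row) {
    if (any(!is.finite(row))) NA_real_ else esm2_score(row)
  })
  profile$score <- unname(scores)
  profile
}

# ---- LLR table serialization -----------------------------------------------

#' Read a per-residue LLR table
#'
#' Tab-separated table with columns `pos` (1-based, contiguous from 1), `wt`
#' (wild-type one-letter code) and the 20 canonical amino-acid columns, in
#' any column order (matched by header). The wild-type column of each row
#' must be 0 within 1e-9.
#'
#' @param path File path.
#' @param protein_id Identifier for the resulting profile; defaults to the
#'   file name without extension.
#' @return A `residue_profile` with `sequence` and `llr` populated.
#' @export
read_llr_table <- function(path, protein_id = NULL) {
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("pos", "wt", aa_alphabet())
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("LLR table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  pos <- as.integer(tab$pos)
  if (!identical(pos, seq_len(nrow(tab)))) {
    gap <- which(pos != seq_along(pos))[1]
    stop("LLR table positions must be contiguous from 1; first problem at ",
         "row ", gap, " (pos = ", pos[gap], ")")
  }
  wt <- toupper(as.character(tab$wt))
  bad <- which(!is_canonical_aa(wt) & !(wt %in% c("X", "U", "B", "Z", "O", "J")))
  if (length(bad))
    stop("unknown amino-acid letter '", wt[bad[1]], "' at row ", bad[1])
  llr <- as.matrix(tab[, aa_alphabet(), drop = FALSE])
  storage.mode(llr) <- "double"
  wt_col <- match(wt, aa_alphabet())
  for (i in seq_along(wt)) {
    if (!is.na(wt_col[i]) && is.finite(llr[i, wt_col[i]]) &&
        abs(llr[i, wt_col[i]]) > 1e-9)
      stop("wild-type LLR is ", llr[i, wt_col[i]], " (expected 0) at row ", i,
           " of ", path)
  }
  residue_profile(protein_id, paste(wt, collapse = ""), llr = llr)
}

#' Write a per-residue LLR table
#'
#' Serialises the LLR matrix with 17 significant digits so that
#' `read_llr_table(write_llr_table(x))` round-trips to full double precision.
#'
#' @param profile A `residue_profile` with `llr` present.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_llr_table <- function(profile, path) {
  stopifnot(inherits(profile, "residue_profile"), !is.null(profile$llr))
  wt <- profile_residues(profile)
  out <- data.frame(pos = seq_along(wt), wt = wt, stringsAsFactors = FALSE)
  num <- apply(profile$llr, 2L, function(col)
    ifelse(is.na(col), "NA", formatC(col, digits = 17, format = "g")))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1L)  # 1-residue edge case
  colnames(num) <- aa_alphabet()
  out <- cbind(out, as.data.frame(num, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pLDDT and sequence ingestion ------------------------------------------

#' Read a per-residue pLDDT track from a TSV
#'
#' Expects columns `pos` (1-based contiguous) and `plddt`.
#'
#' @param path File path.
#' @return Numeric vector of pLDDT values ordered by position.
#' @export
read_plddt_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pos", "plddt") %in% names(tab)))
    stop("pLDDT table must have columns 'pos' and 'plddt'")
  pos <- as.integer(tab$pos)
  if (!identical(pos, seq_len(nrow(tab))))
    stop("pLDDT table positions must be contiguous from 1")
  as.numeric(tab$plddt)
}

#' Extract a pLDDT track from a predicted-structure PDB file
#'
#' In AlphaFold model files the per-atom temperature-factor (B-factor) field
#' carries pLDDT; the per-residue value is taken from the CA atom.
#'
#' @param path PDB file path.
#' @return Numeric vector of per-residue pLDDT in residue order.
#' @export
read_plddt_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca[, c("chain", "resno")]), , drop = FALSE]
  as.numeric(ca$b)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Build a profile from a language-model adapter
#'
#' Adapter seam for plugging in a protein language model. `model` is any
#' function mapping a sequence string to an L x 20 matrix of per-position
#' log-probabilities over [aa_alphabet()]. The LLR at (i, a) is
#' `logP(a at i) - logP(wt_i at i)`, so wild-type entries are exactly 0 by
#' construction. `masking_mode` records whether the model scored each
#' position with the residue masked or visible; it is passed to the model
#' as an attribute of the call and stored on the result.
#'
#' @param sequence Amino-acid string.
#' @param model Callable `function(sequence, masking_mode)` returning an
#'   L x 20 log-probability matrix, or `NULL`.
#' @param masking_mode `"masked"` (default) or `"wildtype"`.
#' @param protein_id Identifier for the profile.
#' @return A scored `residue_profile`.
#' @export
lm_adapter <- function(sequence, model, masking_mode = c("masked", "wildtype"),
                       protein_id = "query") {
  masking_mode <- match.arg(masking_mode)
  if (is.null(model) || !is.function(model))
    stop("no language model available; supply LLR tables via read_llr_table()")
  logp <- model(sequence, masking_mode)
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  if (!is.matrix(logp) || nrow(logp) != length(seq_chars) || ncol(logp) != 20L)
    stop("model must return an L x 20 log-probability matrix")
  wt_col <- match(seq_chars, aa_alphabet())
  llr <- logp - logp[cbind(seq_len(nrow(logp)), wt_col)]
  prof <- residue_profile(protein_id, sequence, llr = llr)
  attr(prof, "masking_mode") <- masking_mode
  score_profile(prof)
}
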