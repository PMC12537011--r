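# Independent oracles, written as straight-line transcriptions of the
# definitions and kept deliberately separate from the package's code paths.

# Softmax entropy computed directly from the printed formula, no
# log-sum-exp stabilisation.
oracle_entropy <- function(v) {
  p <- exp(v) / sum(exp(v))
  -sum(p * log(p))
}

# Column-counting conservation oracle: loop over reference non-gap columns
# and query rows one character at a time.
oracle_conservation <- function(ref_row, query_rows) {
  ref <- strsplit(ref_row, "")[[1]]
  qs <- lapply(query_rows, function(r) strsplit(r, "")[[1]])
  cols <- which(ref != "-")
  cs <- numeric(0); support <- integer(0)
  for (j in cols) {
    n_res <- 0L; n_match <- 0L
    for (q in qs) {
      if (q[j] != "-") {
        n_res <- n_res + 1L
        if (q[j] == ref[j] && q[j] != "X") n_match <- n_match + 1L
      }
    }
    support <- c(support, n_res)
    cs <- c(cs, if (n_res == 0L) NA_real_ else n_match / n_res)
  }
  list(cs = cs, support = support)
}

# Straight-line transcription of the motif-identification procedure:
# one directional pass.
oracle_one_pass <- function(scores, thr) {
  n <- length(scores)
  members <- logical(n)
  pos <- 1
  while (pos <= n) {
    if (!is.na(scores[pos]) && scores[pos] <= thr) {
      seg <- c()
      k <- pos
      while (k <= n && !is.na(scores[k]) &&
             mean(c(seg, scores[k])) <= thr) {
        seg <- c(seg, scores[k])
        k <- k + 1
      }
      members[pos:(k - 1)] <- TRUE
      pos <- k
    } else {
      pos <- pos + 1
    }
  }
  which(members)
}

# Full transcription: both passes, residue intersection, run re-extraction,
# mean filter, iterative merge, length filter.
oracle_find_motifs <- function(scores, thr = 0.5, gap_max = 8, min_len = 4) {
  fwd <- oracle_one_pass(scores, thr)
  rev_members <- length(scores) + 1 - oracle_one_pass(rev(scores), thr)
  common <- sort(intersect(fwd, rev_members))
  segs <- list()
  if (length(common)) {
    run_start <- common[1]
    prev <- common[1]
    for (x in common[-1]) {
      if (x != prev + 1) {
        segs[[length(segs) + 1]] <- c(run_start, prev)
        run_start <- x
      }
      prev <- x
    }
    segs[[length(segs) + 1]] <- c(run_start, prev)
  }
  segs <- Filter(function(s) mean(scores[s[1]:s[2]]) <= thr, segs)
  # merge the eligible adjacent pair with the smallest spanning mean first
  # (ties: smaller gap, then leftmost), until no pair qualifies
  while (length(segs) >= 2) {
    best <- NULL
    best_key <- c(Inf, Inf, Inf)
    for (i in seq_len(length(segs) - 1)) {
      a <- segs[[i]]; b <- segs[[i + 1]]
      gp <- b[1] - a[2] - 1
      mn <- mean(scores[a[1]:b[2]])
      if (gp <= gap_max && !is.na(mn) && mn < thr) {
        key <- c(mn, gp, i)
        if (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2]) ||
            (key[1] == best_key[1] && key[2] == best_key[2] &&
               key[3] < best_key[3])) {
          best <- i
          best_key <- key
        }
      }
    }
    if (is.null(best)) break
    segs[[best]] <- c(segs[[best]][1], segs[[best + 1]][2])
    segs[[best + 1]] <- NULL
  }
  segs <- Filter(function(s) s[2] - s[1] + 1 >= min_len, segs)
  if (!length(segs))
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = vapply(segs, `[`, 0, 1), end = vapply(segs, `[`, 0, 2))
}

# Residue-set oracle for IDR role classification.
oracle_idr_role <- function(idr, ps_list) {
  idr_res <- seq(idr[1], idr[2])
  best <- 0
  for (ps in ps_list) {
    ps_res <- seq(ps[1], ps[2])
    best <- max(best, length(intersect(idr_res, ps_res)) / length(ps_res))
  }
  role <- if (best > 0.5) "driving" else if (best > 0) "participating"
          else "non_participating"
  list(role = role, fraction = best)
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  mu <- n_a * length(b) / 2
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random score track with low-score patches, for motif equivalence trials.
random_score_track <- function(L) {
  s <- runif(L, 0, 3)
  n_patch <- sample(0:3, 1)
  for (p in seq_len(n_patch)) {
    w <- sample(2:12, 1)
    st <- sample(seq_len(max(1, L - w)), 1)
    s[st:(st + w - 1)] <- runif(w, 0, 0.6)
  }
  s
}

# Small random MSA with gaps, gap-only columns and optional all-gap rows.
random_msa_rows <- function(n_q, W) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  ref <- sample(aa, W, replace = TRUE)
  gap_only <- runif(W) < 0.05
  rows <- vapply(seq_len(n_q), function(k) {
    q <- ifelse(runif(W) < 0.6, ref, sample(aa, W, replace = TRUE))
    q[runif(W) < 0.2 | gap_only] <- "-"
    paste(q, collapse = "")
  }, character(1))
  names(rows) <- paste0("q", seq_len(n_q))
  list(ref = paste(ref, collapse = ""), rows = rows)
}
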