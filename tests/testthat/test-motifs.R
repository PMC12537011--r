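test_that("directional scan follows the running-average rule", {
  # all admissible / none admissible
  expect_equal(scan_direction(rep(0.1, 6)), 1:6)
  expect_equal(scan_direction(rep(1.0, 6)), integer())
  expect_equal(scan_direction(numeric()), integer())
  # an average of exactly 0.5 does not breach: 0.1, 0.9 -> avg 0.5 -> keep
  expect_equal(scan_direction(c(0.1, 0.9, 0.1)), 1:3)
  # breach ends the candidate before the breaching residue
  expect_equal(scan_direction(c(0.1, 2.0, 0.1)), c(1L, 3L))
  # mirror image: backward pass equals forward pass on the reversed track
  s <- c(0.9, 0.1, 0.1, 2.0, 0.3)
  expect_equal(scan_direction(s, direction = "backward"),
               sort(length(s) + 1L - oracle_one_pass(rev(s), 0.5)))
})

test_that("find_motifs handles the documented merge scenarios", {
  # uniform low track: one motif spanning everything
  m <- find_motifs(rep(0.2, 10))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 10L))
  expect_equal(m$mean_score, 0.2)
  # two low runs separated by 5 mild residues: spanning mean < 0.5 -> merge
  tr <- c(rep(0.1, 5), rep(0.4, 5), rep(0.1, 5))
  m2 <- find_motifs(tr)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$length, 15L)
  expect_equal(m2$mean_score, mean(tr))
  # same gap but hostile: spanning mean > 0.5 blocks the merge
  tr3 <- c(rep(0.1, 5), rep(5.0, 5), rep(0.1, 5))
  m3 <- find_motifs(tr3)
  expect_equal(nrow(m3), 2L)
  expect_equal(m3$start, c(1L, 11L))
  expect_equal(m3$end, c(5L, 15L))
  # a single breaching residue (2.6 > the running-average budget) splits the
  # scans into two candidates, but gap 1 <= 8 and spanning mean 0.33 < 0.5
  # merge them back into one motif
  tr4 <- c(rep(0.1, 5), 2.6, rep(0.1, 5))
  m4 <- find_motifs(tr4, merge_gap = 8)
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$length, 11L)
  expect_equal(m4$mean_score, mean(tr4))
  # 9 intervening breaching residues exceed merge_gap: runs stay separate
  tr5 <- c(rep(0.1, 5), rep(2.6, 9), rep(0.1, 5))
  m5 <- find_motifs(tr5, merge_gap = 8)
  expect_equal(nrow(m5), 2L)
  expect_equal(m5$start, c(1L, 15L))
  # same geometry under a merge_gap of 9 is still blocked by the span mean
  expect_equal(nrow(find_motifs(tr5, merge_gap = 9)), 2L)
})

test_that("emitted motifs respect the mean-score and length contracts", {
  set.seed(31)
  for (trial in 1:100) {
    s <- random_score_track(sample(10:200, 1))
    m <- find_motifs(s)
    if (nrow(m)) {
      expect_true(all(m$mean_score <= 0.5))
      expect_true(all(m$length >= 4))
      expect_true(all(m$end - m$start + 1L == m$length))
      if (nrow(m) > 1) expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    }
    # determinism
    expect_identical(find_motifs(s), m)
  }
})

test_that("find_motifs equals the straight-line transcription oracle", {
  set.seed(97)
  for (trial in 1:300) {
    s <- random_score_track(sample(5:200, 1))
    got <- find_motifs(s)
    exp <- oracle_find_motifs(s)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
  }
})

test_that("reversing the track mirrors the motif set", {
  set.seed(55)
  for (trial in 1:50) {
    s <- random_score_track(sample(10:150, 1))
    m <- find_motifs(s)
    mr <- find_motifs(rev(s))
    L <- length(s)
    expect_equal(sort(L + 1 - c(mr$end, mr$start)),
                 sort(c(m$start, m$end)))
  }
})

test_that("raising the threshold never removes pre-merge motif residues", {
  set.seed(71)
  for (trial in 1:30) {
    s <- random_score_track(80)
    lo <- intersect(scan_direction(s, 0.4),
                    scan_direction(s, 0.4, "backward"))
    hi <- intersect(scan_direction(s, 0.6),
                    scan_direction(s, 0.6, "backward"))
    expect_true(all(lo %in% hi))
  }
})

test_that("profile motif search reports protein coordinates and sequences", {
  L <- 40
  plddt <- c(rep(90, 10), rep(50, 20), rep(90, 10))
  score <- c(rep(0.1, 10), rep(2.5, 5), rep(0.2, 8), rep(2.5, 7),
             rep(0.1, 10))
  seq <- paste(rep(aa_alphabet()[1:20], 2), collapse = "")
  prof <- residue_profile("prot", seq, plddt = plddt)
  prof$score <- score
  m <- find_profile_motifs(prof)
  # only the IDR (11-30) is scanned; motif = positions 16-23
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(16L, 23L))
  expect_equal(m$sequence, substr(seq, 16, 23))
  # whole-protein scan additionally finds the folded termini
  m2 <- find_profile_motifs(prof, whole_protein = TRUE)
  expect_gt(nrow(m2), 1L)
})

test_that("per-amino-acid conserved-in-motif fractions count correctly", {
  # 10 conserved alanines, 9 inside the motif interval
  seqs <- paste(c(rep("A", 10), rep("G", 4), "A"), collapse = "")
  prof <- residue_profile("p", seqs)
  prof$score <- c(rep(0.1, 10), rep(0.1, 4), 0.1)
  motifs <- data.frame(start = 1L, end = 14L)
  fr <- fraction_conserved_in_motifs(prof, motifs)
  expect_equal(fr[["A"]], 10 / 11)
  expect_equal(fr[["G"]], 1.0)
  expect_true(is.na(fr[["W"]]))   # no conserved tryptophans anywhere
  # conserved means strictly below the cutoff here
  prof$score[15] <- 0.5
  fr2 <- fraction_conserved_in_motifs(prof, motifs)
  expect_equal(fr2[["A"]], 1.0)   # the 0.5 residue no longer counts
})
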