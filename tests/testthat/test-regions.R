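test_that("segment sets normalize: merge, sort, validate", {
  s <- segment_set("P", c(10, 3, 5), c(14, 6, 8), "idr")
  expect_equal(s$start, c(3L, 10L))   # 3-6 and 5-8 merge to 3-8
  expect_equal(s$end, c(8L, 14L))
  expect_error(segment_set("P", 0, 5, "idr"), "start")
  expect_error(segment_set("P", 5, 4, "idr"), "start")
  # different labels never merge
  s2 <- segment_set("P", c(1, 1), c(5, 5), c("idr", "ps_segment"))
  expect_equal(nrow(s2), 2L)
})

test_that("IDR role classification follows the over-50% rule", {
  ps <- segment_set("P", 11, 20, "ps_segment")   # length 10
  # IDR covering 8 of 10 PS residues -> driving
  expect_equal(classify_idr_role(c(13, 40), ps)$role, "driving")
  # disjoint -> non_participating
  r <- classify_idr_role(c(30, 40), ps)
  expect_equal(r$role, "non_participating")
  expect_equal(r$overlap_fraction, 0)
  # exactly 50% -> participating (driving requires strictly more)
  r2 <- classify_idr_role(c(16, 40), ps)
  expect_equal(r2$overlap_fraction, 0.5)
  expect_equal(r2$role, "participating")
  # empty PS set
  expect_equal(classify_idr_role(c(1, 5), segment_set())$role,
               "non_participating")
  # one residue of overlap is enough to participate
  expect_equal(classify_idr_role(c(20, 25), ps)$role, "participating")
})

test_that("role classification agrees with the residue-set oracle", {
  set.seed(17)
  for (trial in 1:200) {
    L <- sample(20:60, 1)
    idr_s <- sample(L - 1, 1); idr_e <- sample(idr_s:L, 1)
    n_ps <- sample(1:3, 1)
    ps_list <- lapply(seq_len(n_ps), function(i) {
      s <- sample(L - 1, 1); c(s, sample(s:L, 1))
    })
    ps <- segment_set("P", vapply(ps_list, `[`, 0, 1),
                      vapply(ps_list, `[`, 0, 2), "ps_segment")
    # oracle on the *normalized* segments (merged same-label intervals)
    ps_norm <- lapply(seq_len(nrow(ps)), function(i) c(ps$start[i], ps$end[i]))
    got <- classify_idr_role(c(idr_s, idr_e), ps)
    exp <- oracle_idr_role(c(idr_s, idr_e), ps_norm)
    expect_identical(got$role, exp$role)
    expect_equal(got$overlap_fraction, exp$fraction)
  }
})

test_that("greedy redundancy filter retains the documented subset", {
  # identical pair: second (by sorted id) dropped
  seqs <- c(B = "MKVLITAGPTREALDPVRYISNHSSGKMGFAIAEAAAR",
            A = "MKVLITAGPTREALDPVRYISNHSSGKMGFAIAEAAAR")
  expect_equal(redundancy_filter(seqs), "A")
  # unrelated sequences all retained
  seqs2 <- c(A = "MKVLITAGPTREALDPVRYISNHSSGKMGF",
             B = "WWDDNNGGHHEEPPQQYYCCSSTTIIKKRR",
             C = "GAVLIPFMWSTCYNQDEKRHGAVLIPFMWS")
  expect_equal(redundancy_filter(seqs2), c("A", "B", "C"))
  # constructed triple: (A,B) redundant, (A,C) and (B,C) not -> {A, C}
  base <- "MKVLITAGPTREALDPVRYISNHSSGKMGFAIAEAAARGAVLIPFMWSTC"
  near <- paste0(substr(base, 1, 40), "WWWWWWWWWW")   # ~80% identical to base
  far <- "HHEEPPQQYYCCSSTTIIKKRRHHEEPPQQYYCCSSTTIIKKRRHHEEPP"
  ids <- redundancy_filter(c(A = base, B = near, C = far))
  expect_equal(ids, c("A", "C"))
  # invariant: no retained pair above the cutoff
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    seqs3 <- c(A = base, B = near, C = far)
    expect_lte(pairwise_identity(seqs3[[ids[i]]], seqs3[[ids[j]]]), 0.5)
  }
})

test_that("PS overlap filter needs at least one shared residue", {
  idrs <- list(
    p1 = segment_set("p1", 1, 10, "idr"),
    p2 = segment_set("p2", 1, 10, "idr"),
    p3 = segment_set("p3", 1, 10, "idr"))
  ps <- list(
    p1 = segment_set("p1", 10, 20, "ps_segment"),  # 1-residue overlap
    p2 = segment_set("p2", 11, 20, "ps_segment"),  # none
    p3 = segment_set())                            # none annotated
  expect_equal(ps_overlap_filter(idrs, ps), "p1")
})

test_that("conserved-in-PS probability partitions conserved residues", {
  # 30 residues, disordered block 1-20, PS segment 6-15 (IDR covers 100%)
  prof <- residue_profile("p", strrep("A", 30),
                          plddt = c(rep(50, 20), rep(90, 10)))
  prof$score <- rep(2.5, 30)
  conserved_pos <- c(2, 6, 8, 10, 12, 14, 18, 20)   # 8 conserved, 5 in 6-15
  prof$score[conserved_pos] <- 0.2
  # place PS so that driving/participating union is 6-15... the single IDR
  # 1-20 covers all of PS 6-15 -> driving, union = IDR 1-20
  ps <- segment_set("p", 6, 15, "ps_segment")
  expect_equal(conserved_in_ps_probability(prof, ps), 1.0)
  # no overlap: IDR is non-participating -> p = 0
  ps2 <- segment_set("p", 25, 30, "ps_segment")
  expect_equal(conserved_in_ps_probability(prof, ps2), 0.0)
  # split disorder: IDRs 1-10 and 16-25; PS 1-15 (length 15) -> IDR1 covers
  # 10/15 > 0.5 (driving), IDR2 disjoint (non-participating). Conserved
  # disordered residues at 2,4,6,8,10 (inside the union) and 17,19,21
  # (outside): p = 5/8
  prof2 <- residue_profile("p", strrep("A", 30),
                           plddt = c(rep(50, 10), rep(90, 5), rep(50, 10),
                                     rep(90, 5)))
  prof2$score <- rep(2.5, 30)
  prof2$score[c(2, 4, 6, 8, 10, 17, 19, 21)] <- 0.2
  ps3 <- segment_set("p", 1, 15, "ps_segment")
  expect_equal(conserved_in_ps_probability(prof2, ps3), 0.625)
  # no conserved disordered residues -> NA
  prof3 <- prof
  prof3$score <- rep(2.5, 30)
  expect_true(is.na(conserved_in_ps_probability(prof3, ps)))
  # complement identity: p + (1 - p) == 1 trivially; check p for a mixed case
  prof4 <- residue_profile("p", strrep("A", 40),
                           plddt = c(rep(50, 30), rep(90, 10)))
  prof4$score <- rep(2.5, 40)
  prof4$score[c(1:5, 21:23)] <- 0.2   # 8 conserved disordered
  ps4 <- segment_set("p", 1, 8, "ps_segment")
  # IDR 1-30 covers PS fully -> driving; union = 1-30 -> all 8 inside
  expect_equal(conserved_in_ps_probability(prof4, ps4), 1.0)
})

test_that("BED round trip preserves 1-based inclusive coordinates", {
  s <- segment_set(c("P1", "P2"), c(3, 7), c(9, 12),
                   c("idr", "ps_segment"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(s, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, s$start - 1L)   # 0-based half-open on disk
  expect_equal(bed$V3, s$end)
  back <- read_segments_bed(path)
  expect_equal(back$start, s$start)
  expect_equal(back$end, s$end)
  expect_equal(back$label, s$label)
})
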