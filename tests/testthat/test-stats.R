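test_that("group comparison handles degenerate and separated groups", {
  same <- group_compare(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_equal(same$significance_label, "n.s.")
  # fully separated tie-free groups: U = 0, exact two-sided p = 2/20
  sep <- group_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$u_statistic, 0)
  expect_equal(sep$p_value, 2 / choose(6, 3))
  expect_error(group_compare(numeric(), 1:3), "non-empty")
})

test_that("small tie-free comparisons match exact enumeration", {
  set.seed(13)
  for (trial in 1:40) {
    n_a <- sample(2:5, 1); n_b <- sample(2:5, 1)
    x <- sample(seq(1, 300), n_a + n_b)   # distinct values, no ties
    a <- x[seq_len(n_a)]; b <- x[-seq_len(n_a)]
    got <- group_compare(a, b)
    expect_equal(got$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("null simulations rarely reach extreme significance", {
  set.seed(29)
  p <- replicate(300, group_compare(rnorm(30), rnorm(30))$p_value)
  expect_gte(mean(p > 0.001), 0.99)
})

test_that("significance labels use the standard cutpoints", {
  expect_equal(significance_label(0.0005), "***")
  expect_equal(significance_label(0.005), "**")
  expect_equal(significance_label(0.02), "*")
  expect_equal(significance_label(0.07), "†")
  expect_equal(significance_label(0.2), "n.s.")
  expect_equal(significance_label(0.10), "n.s.")  # boundary: p >= 0.10
})

make_llr_profile <- function(id, seq_chars, scores, plddt) {
  wt <- match(seq_chars, aa_alphabet())
  llr <- t(vapply(seq_along(wt), function(i)
    make_llr_for_score(scores[i], wt[i]), numeric(20)))
  p <- score_profile(residue_profile(id, paste(seq_chars, collapse = ""),
                                     plddt = plddt, llr = llr))
  p
}

test_that("per-amino-acid correlation recovers a perfect linear relation", {
  # one residue per type; score rising with index, conservation falling
  aa <- setdiff(aa_alphabet(), "M")
  scores <- seq(0.2, 2.8, length.out = 19)
  prof <- make_llr_profile("lin", aa, scores, rep(60, 19))
  cs <- data.frame(pos = 1:19, ref_aa = aa, cs = 1 - scores / 3,
                   support = 50L)
  res <- aa_correlation(list(lin = prof), list(lin = cs))
  expect_equal(res$r, -1.0, tolerance = 1e-10)
  expect_equal(res$n_aa, 19L)
})

test_that("correlation drops excluded and absent amino acids", {
  aa <- c("A", "C", "D", "M")
  prof <- make_llr_profile("m", aa, c(0.5, 1, 1.5, 2), rep(60, 4))
  cs <- data.frame(pos = 1:4, ref_aa = aa, cs = c(0.9, 0.6, 0.3, 0.1),
                   support = 10L)
  res <- aa_correlation(list(m = prof), list(m = cs))
  expect_equal(res$n_aa, 3L)   # M excluded
  # a single type left is degenerate -> NA with warning
  prof2 <- make_llr_profile("s", c("A", "A"), c(0.5, 0.7), rep(60, 2))
  cs2 <- data.frame(pos = 1:2, ref_aa = "A", cs = c(0.9, 0.8), support = 5L)
  expect_warning(res2 <- aa_correlation(list(s = prof2), list(s = cs2)),
                 "too few")
  expect_true(is.na(res2$r))
})

test_that("mean LLR aggregation matches brute force and zeroes the diagonal", {
  set.seed(19)
  profs <- lapply(1:3, function(k) {
    L <- 30
    wt <- sample(20, L, replace = TRUE)
    llr <- matrix(rnorm(L * 20), L, 20)
    llr[cbind(1:L, wt)] <- 0
    residue_profile(paste0("p", k), paste(aa_alphabet()[wt], collapse = ""),
                    llr = llr)
  })
  names(profs) <- vapply(profs, `[[`, "", "protein_id")
  got <- mean_llr_by_aa(profs)
  # brute force accumulation
  aa <- aa_alphabet()
  for (a in aa) {
    rows <- do.call(rbind, lapply(profs, function(p) {
      idx <- which(profile_residues(p) == a)
      p$llr[idx, , drop = FALSE]
    }))
    if (nrow(rows) == 0) {
      expect_true(all(is.na(got[a, ])))
    } else {
      expect_equal(unname(got[a, ]), unname(colMeans(rows)))
      expect_identical(unname(got[a, a]), 0)
    }
  }
  # two alanines average elementwise
  v1 <- c(0, rnorm(19)); v2 <- c(0, rnorm(19))
  pa <- residue_profile("aa", "AA", llr = rbind(v1, v2))
  expect_equal(unname(mean_llr_by_aa(list(pa))["A", ]), (v1 + v2) / 2)
  # region masks restrict the accumulation
  masked <- mean_llr_by_aa(list(aa = pa), list(aa = c(TRUE, FALSE)))
  expect_equal(unname(masked["A", ]), v1)
})

test_that("embedding and clustering separate constructed groups", {
  set.seed(23)
  centers <- matrix(rnorm(5 * 20, sd = 0), 5, 20)
  centers[cbind(1:5, 1:5)] <- 40 * (1:5)   # 5 well-separated directions
  m <- centers[rep(1:5, each = 4), ] + matrix(rnorm(20 * 20, sd = 0.01),
                                              20, 20)
  rownames(m) <- aa_alphabet()
  res <- embed_and_cluster(m, n_clusters = 5)
  truth <- rep(1:5, each = 4)
  # same partition up to label renaming
  expect_equal(length(unique(res$cluster)), 5L)
  expect_true(all(tapply(res$cluster, truth, function(x)
    length(unique(x))) == 1))
  # determinism
  expect_identical(embed_and_cluster(m, n_clusters = 5)$cluster,
                   res$cluster)
  # identical rows collapse to a single cluster
  flat <- matrix(1, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  expect_equal(unique(embed_and_cluster(flat)$cluster), 1L)
  # missing rows are refused
  m2 <- m; m2[3, ] <- NA
  expect_error(embed_and_cluster(m2), "missing")
})

test_that("density surface normalizes, masks empty bins, exposes levels", {
  # all mass in one bin
  s <- density_surface(rep(c(0, 1), c(49, 1)), rep(c(0, 1), c(49, 1)),
                       bins = 10)
  occupied <- which(!is.na(s$neg_log_p))
  bin_area <- diff(s$x_breaks)[1] * diff(s$y_breaks)[1]
  # two occupied bins (corner clusters); check -log P of the heavy one
  expect_equal(min(s$neg_log_p, na.rm = TRUE),
               -log((49 / 50) / bin_area))
  # empty bins masked, never -log(0)
  expect_true(all(is.finite(s$neg_log_p[occupied])))
  # uniform points give a near-flat surface
  set.seed(37)
  s2 <- density_surface(runif(2e5), runif(2e5), bins = 10)
  rng <- range(s2$neg_log_p, na.rm = TRUE)
  expect_lt(diff(rng), 0.5)
  expect_equal(diff(attr(s2$neg_log_p, "levels"))[1], 0.5)
  expect_error(density_surface(1, 1), "at least 2")
})
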