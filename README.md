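# idrtol — mutational tolerance and conserved motifs in disordered regions

`idrtol` is an R package for analysing the mutational landscape of
intrinsically disordered protein regions (IDRs). Protein language models
assign every position a 20-element vector of log-likelihood ratios (LLRs)
between each possible substitution and the wild-type residue. `idrtol`
condenses that vector into a per-residue **tolerance score** — the Shannon
entropy of the softmax of the LLRs,

$$S_i = -\sum_{a=1}^{20} p_{ia}\ln p_{ia}, \qquad
  p_{ia} = \frac{e^{\mathrm{LLR}_i(a)}}{\sum_b e^{\mathrm{LLR}_i(b)}}
  \in [0,\,\ln 20],$$

so that mutationally constrained residues score near 0 and fully tolerant
residues near ln 20 ≈ 3.0 — and builds the downstream analyses on top of it:

* residue classification by structural order (pLDDT ≤ 70 = disordered) and
  constraint (score ≤ 0.5 conserved, ≥ 2.0 flexible), IDR extraction, and
  dataset filters (≥ 10% disordered residues, ≤ 50% pairwise identity);
* per-position **conservation scores** from multiple sequence alignments
  (A3M / CLUSTAL / aligned FASTA), CS_i = matches / non-gap homolog
  residues, with a > 20%-identity homolog filter;
* IDR **role classification** against experimentally annotated
  phase-separation segments (driving > 50% coverage of a segment,
  participating > 0%, non-participating 0%);
* **motif detection**: maximal contiguous stretches with average score
  ≤ 0.5, found by a bidirectional scan, residue-level intersection,
  proximity merging (≤ 8 intervening residues) and a minimum length of 4;
* aggregate statistics: Mann–Whitney U group comparisons with significance
  labels, per-amino-acid score–conservation correlations by pLDDT stratum,
  20×20 mean-LLR matrices with embedding + clustering, and −log P density
  surfaces;
* a seeded **synthetic-data generator** that plants all of this structure
  (bimodal score populations, conservation anticorrelated with score,
  driver IDRs shifted toward low scores, conserved motifs inside flexible
  IDRs) so the entire pipeline is testable without external databases.

## Worked example

Generate a small labelled dataset (2 drivers, 2 clients, 2 controls) and run
every stage:

```r
library(idrtol)

spec <- synthetic_spec(seed = 42, n_proteins = 2L, n_queries = 50L)
make_dataset(spec, "demo_data")
res <- run_pipeline("demo_data", default_config(out_dir = "demo_run"))

res$motifs[1:3, ]
#>   protein_id start end length      sequence mean_score
#> 1     SYN001   112 120      9     LKHGYIFWY  0.2487167
#> 2     SYN002   110 122     13 PIMQVMAMKWQCM  0.2621195
#> 3     SYN003    87  95      9     YPEHVQRKV  0.2209605

res$comparisons[, c(1, 2, 5, 6, 7)]
#>                                     group_a_name      group_b_name u_statistic      p_value significance_label
#> driving_vs_participating                 driving     participating        1795 2.320883e-04                ***
#> driving_vs_non_participating             driving non_participating        6784 1.152059e-29                ***
#> participating_vs_non_participating participating non_participating        4439 1.496284e-03                 **

res$aa_correlation
#>   stratum          r n_aa
#> 1       1 -0.9325836   19
#> 2       2 -0.9605384   19
#> 3       3 -0.8342391   19
#> 4       4 -0.6587606   19
```

Reading the output: each detected motif is a contiguous constrained stretch
(mean score ≤ 0.5) inside an extracted IDR, reported in 1-based residue
coordinates with its subsequence. The comparisons table shows that residues
of driving IDRs score significantly lower (more constrained) than those of
participating and non-participating IDRs — the planted group effect — and
`aa_correlation` shows the strong anticorrelation between mean tolerance
score and mean alignment conservation of the 19 amino-acid types
(methionine excluded), within each pLDDT stratum. All stage outputs
(residue classes, IDR roles, motif CSV, conservation TSVs, comparison
table, mean-LLR matrix, density surface, resolved config, run log) are
written under `demo_run/`.

Individual operations are exported too:

```r
esm2_score(rep(0, 20))        # 2.995732 = ln 20: uniform LLRs, full tolerance
m  <- parse_alignment("demo_data/SYN001.a3m", "a3m")
cs <- conservation_scores(filter_homologs(m, 0.20))
cor(cs$cs, res$profiles[["SYN001"]]$score, use = "complete.obs")
#> -0.966
```

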