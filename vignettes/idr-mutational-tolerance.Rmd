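---
title: "Methods: mutational tolerance and conserved motifs in disordered regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational tolerance and conserved motifs in disordered regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrtol)
```

## The problem

Intrinsically disordered regions (IDRs) lack a stable fold, evolve quickly,
and are generally tolerant of substitutions — yet some disordered residues
are under strong constraint, and those constrained stretches are enriched in
regions that drive the formation of membraneless organelles by liquid–liquid
phase separation. `idrtol` implements an alignment-free way of finding such
residues from protein language-model predictions, an alignment-based
conservation score to validate them, a scheme for classifying IDRs by their
overlap with experimentally annotated phase-separation (PS) segments, and a
motif detector that extracts contiguous constrained stretches.

## The tolerance score

A language model scanned over a protein yields, at every position $i$, a
20-element vector of log-likelihood ratios
$\mathrm{LLR}_i(a) = \log P(a \mid i) - \log P(\mathrm{wt}_i \mid i)$,
with the wild-type entry identically 0. The per-residue score is the
Shannon entropy of the softmax of that vector:

$$
S_i \;=\; -\sum_{a=1}^{20} p_{ia}\,\ln p_{ia},
\qquad
p_{ia} \;=\; \frac{e^{\mathrm{LLR}_i(a)}}{\sum_{b=1}^{20} e^{\mathrm{LLR}_i(b)}}.
$$

$S_i \in [0, \ln 20 \approx 3.00]$: a uniform mutation preference gives the
maximum (full tolerance), a single dominant residue drives it to 0 (strong
constraint). The natural logarithm is the right base: the empirical score
axis spans roughly 0–3 and the flexible-population cutoff of 2.0 only makes
sense against a ceiling of $\ln 20$. The sum runs over all 20 amino acids
including the wild type, whose LLR is 0 by construction. The score is
invariant to adding a constant to the LLR vector and to permuting it;
`esm2_score()` computes it with log-sum-exp stabilisation so that both
invariances hold to better than $10^{-12}$.

Nonstandard residues (X, U, B, Z…) keep their coordinate but carry `NA`
scores and are excluded from every aggregation — the entropy is defined only
over the canonical alphabet.

## Thresholds and residue classes

All thresholds are parameters with the conventional defaults:

| parameter | default | meaning |
|---|---|---|
| `plddt_cut` | 70 | disordered iff pLDDT ≤ 70 (inclusive) |
| `conserved_cut` | 0.5 | conserved iff score ≤ 0.5 |
| `flexible_cut` | 2.0 | flexible iff score ≥ 2.0 |
| `identity_min` | 0.20 | homologs at ≤ 20% identity are dropped (strict >) |
| `overlap_driving` | 0.5 | driving iff IDR covers > 50% of a PS segment |
| `merge_gap` | 8 | motif merge bridges ≤ 8 intervening residues |
| `motif_min_len` | 4 | shortest reported motif |
| `redundancy_max` | 0.50 | pairwise identity above which proteins are redundant |
| `disordered_frac_min` | 0.10 | minimum disordered fraction to keep a protein |

Threshold inclusivity follows the printed inequality directions throughout
(≤ 70, ≤ 0.5, ≥ 2.0, "over 50%", "≤ 20% removed"). One documented corner:
with the default left-closed pLDDT strata ([0,50), [50,70), [70,90),
[90,100]) a residue at exactly pLDDT 70 lands in stratum 3 although the
order rule calls it disordered; the bin edges are configurable
(`stratum_edges`) since published analyses rarely print them, and 50/90 are
the conventional structure-prediction confidence bands.

## Conservation from alignments

Homolog rows are compared to the reference in aligned coordinates. Percent
identity is matches over the *full* aligned reference length (gap columns
included), so fragmentary homologs score low; rows at or below 20% identity
are removed. The per-position conservation score is

$$
\mathrm{CS}_i = \frac{n_i(\text{query residue} = \text{reference residue})}
                     {N_i(\text{non-gap query residues})},
$$

counted over query rows only — including the reference row would inflate
every position. Columns where all queries are gapped are reported missing,
never imputed, and excluded downstream. Comparison is case-insensitive
after A3M normalization (lowercase insertion characters removed so all rows
align to reference columns); `X` never matches anything.

## IDR roles

An IDR's overlap fraction with a PS segment uses the *PS segment's* length
as denominator — the classification asks how much of the experimentally
validated segment the IDR accounts for. With several PS segments the
maximum fraction wins. Driving requires strictly more than 50%; an exact
50% overlap is participating, and a single shared residue is enough to
participate. Intervals are held 1-based inclusive internally — the native R
and Bioconductor convention, and the one used in published residue numbering
("residues 75–85") — with BED writers converting to 0-based half-open at
the file boundary.

## Motif identification

Motifs are contiguous stretches whose average score is at most 0.5, found
in four steps:

1. **Directional scan.** From one terminus, find the first admissible
   residue (score ≤ 0.5), then append residues toward the other terminus
   while the running average stays ≤ 0.5; the residue that pushes the
   average over closes the candidate, and scanning resumes there. A running
   average of exactly 0.5 does not breach — consistent with the motif
   definition "0.5 or lower".
2. **Bidirectional intersection.** The same scan runs from both termini and
   the residue-index sets are intersected, trimming terminal residues that
   ride along in only one direction. Intersection at residue level (then
   re-extraction of contiguous runs) is the only reading that actually trims
   edges; runs whose mean drifted above 0.5 after trimming are dropped.
3. **Proximity merge.** Two runs merge when at most `merge_gap = 8`
   residues intervene and the spanning segment's mean is strictly below 0.5
   (admission uses ≤, merging uses <; both follow the respective defining
   sentences and are deliberately kept distinct). When several adjacent
   pairs qualify, the pair with the *smallest spanning mean* merges first
   (ties: smaller gap, then leftmost), repeating until no pair qualifies.
   This canonical order was a genuine design decision: a left-to-right
   fixpoint looks natural but makes the result depend on scan direction
   when three or more runs sit close together, breaking the mirror symmetry
   the bidirectional construction promises. Ordering by spanning mean is
   reversal-invariant, keeps every intermediate motif within the score
   contract, and is deterministic.
4. **Length filter.** Motifs shorter than 4 residues are dropped.

The gap distance counts *intervening* residues
(`start_later − end_earlier − 1`); "within eight residues" admits other
readings, so the parameter is configurable. Motif search runs inside IDR
boundaries by default (`find_profile_motifs()`), with a whole-protein flag.

## Group comparisons

Score distributions of driving, participating and non-participating IDRs
are compared with two-sided Mann–Whitney U tests via `stats::wilcox.test`:
exact enumeration for tie-free groups of at most 20 observations each,
normal approximation with tie correction otherwise. When all pooled values
are identical the test statistic carries no information and p = 1 is
reported. Significance labels use the standard cutpoints (*** < 0.001,
** < 0.01, * < 0.05, † < 0.10, n.s. otherwise).

The 20×20 mean-LLR matrix averages each amino-acid type's LLR vectors over
a residue mask (e.g. driving-IDR residues); its diagonal is exactly 0
whenever inputs respect the wild-type-zero invariant. For grouping amino
acids by mutational profile, the 2-D embedder is pluggable; the default is
the first two principal components — deterministic and adequate for
cluster recovery on separated data — followed by average-linkage
hierarchical clustering. The cluster count (default 5) is a display
parameter, not a discovered quantity. Density surfaces are plain 2-D
histograms (equal-width bins, default 100×100 over the observed range)
normalized to integrate to 1 and reported as −log P with empty bins masked
rather than infinite; contour levels at 0.5-unit spacing are attached.

## The synthetic generator

Real inputs for this analysis (language-model LLR matrices, structure-
prediction confidence tracks, deep alignments, curated PS segments) come
from external resources; the generator produces datasets with the same
statistical skeleton so every stage is testable in isolation:

* **Block architecture.** Proteins are concatenations of folded blocks
  (target score mean 0.3, sd 0.15; pLDDT mean 90, sd 5), flexible IDR
  blocks (score mean 2.4, sd 0.3; pLDDT mean 50, sd 10) and planted
  conserved motifs inside IDRs (score mean 0.25, sd 0.1; disordered
  pLDDT). These centres reproduce the bimodal ordered/disordered score
  structure with a conserved-disordered subpopulation; the sds are chosen
  so the populations are distinct but overlapping, as in real data.
* **Score-to-LLR inversion.** `make_llr_for_score()` builds an LLR vector
  with a prescribed entropy by bisection on a one-parameter family
  (non-wild-type entries $-c\,w_k$, $w_k > 0$): the entropy falls
  continuously from $\ln 20$ at $c = 0$ towards 0, so bisection (parameter
  tolerance $10^{-12}$, score error < $10^{-6}$) always lands on target.
  There is no closed-form inverse. Weight jitter adds heterogeneity without
  affecting the guarantee, since any crossing of the target entropy is a
  valid solution.
* **Conservation coupling.** Homolog rows match the reference with
  probability $q_i = \mathrm{clamp}(1 - S_i/\ln 20 + \varepsilon, 0, 1)$,
  $\varepsilon \sim N(0, 0.05)$, plus gaps at rate 0.10 and optional
  lowercase A3M insertions at rate 0.02 — enough alignment pathology to
  exercise the parsers. With 200 homologs the empirical conservation track
  correlates with $q$ above 0.95 and with the score below −0.8.
* **Group effect.** Driver proteins shift their *flexible* IDR blocks down
  by δ = 0.5 (shifting the motif blocks too would only pile them against
  the score floor) and carry a PS segment fully covered by the motif-bearing
  IDR; clients carry one whose IDR overlap is at most 50%; controls carry
  none. δ = 0.5 with 500 residues per group makes the rank-sum comparison
  significant at p < 0.001 essentially always.
* **Determinism.** Entry points taking a `synthetic_spec` seed R's RNG
  once (`set.seed(spec$seed)`); the same spec reproduces byte-identical
  files. Lower-level generators draw from the current stream, the
  idiomatic R equivalent of passing a generator object.

What the generator does *not* emulate: realistic substitution matrices or
phylogenetic correlation between homologs (rows are i.i.d. given $q$), the
covariance structure of real language-model LLRs across positions and
amino-acid types, compositional biases of real IDRs, or structured gaps.
Passing tests therefore demonstrate that the machinery recovers planted
signal under the stated noise model — not that the biological conclusions
transfer to any particular proteome.

## Numerical and degenerate-input choices

* Entropy via log-sum-exp; results clamped to $[0, \ln 20]$ against
  rounding spill.
* LLR tables serialised with 17 significant digits so read∘write is the
  identity on doubles.
* Wild-type LLR entries must be 0 within $10^{-9}$ on ingestion (then
  snapped to exactly 0); violations are format errors naming the row.
* All-gap alignment columns: conservation missing, excluded downstream.
* Empty PS sets: non-participating with overlap 0. Empty score tracks:
  empty motif sets. Degenerate (all-identical) embeddings: a single
  cluster.
* Greedy redundancy filtering processes proteins in sorted-id order for
  determinism; identity is global-alignment matches over the longer
  sequence length (BLOSUM62, gap open 10 / extend 0.5).

## Problem sizes

The test suite verifies the entropy score against an independent
direct-formula oracle on 1,000 random vectors (and one constant frozen from
a 40-digit evaluation), conservation against brute-force column counting on
500 random alignments up to 10×50 (half routed through A3M serialisation
with insertions), the motif finder against an independent transcription of
its definition on 500 random tracks up to length 200, IDR roles against a
residue-set oracle on 1,000 random configurations including exact-50%
boundaries, rank-sum p-values against full enumeration for all tie-free
splits with n ≤ 10, and recovery/determinism of the full pipeline on
generated datasets of 6–18 proteins with 25–200 homologs per alignment.
These sizes keep the whole suite under a minute while leaving each
property's failure modes (ties, boundaries, gap-only columns, merge
cascades) well represented.

## Limitations

The package consumes LLR matrices and pLDDT tracks; it neither runs a
language model nor predicts disorder (the `lm_adapter()` seam accepts any
callable that maps a sequence to per-position log-probabilities). Scores
at the extremes depend on upstream model calibration, and the conservation
score treats homolog rows as independent — deep alignments of close
paralogs will overstate support. The motif definition is purely score
based; detected motifs are candidates for, not evidence of, function.
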