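---
title: "Rank-pair prognostic signatures: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-pair prognostic signatures: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopairs)
```

## The problem

Quantitative expression signatures transfer poorly between transcriptomic
platforms: RNA-seq counts, microarray intensities and different
normalizations place the same biology on different numerical scales.
`reopairs` builds prognostic signatures from *relative expression orderings*
(REO): for a gene pair (A, B) and one sample, the only information used is
whether A's expression exceeds B's within that sample. Any strictly
increasing per-sample distortion — scale, shift, power, exponential, or any
other monotone map a platform might impose — leaves every such comparison
unchanged, so a model built on pair indicators is rank-invariant by
construction and can be applied to a single sample with no normalization.

The package implements the complete workflow for a pyroptosis-focused
lncRNA-pair survival signature in gastric cancer, but every stage is generic
in the gene set and disease.

## Stage 1: pathway-coupled lncRNA discovery

For each lncRNA, all mRNAs are ranked by their correlation with that lncRNA
across tumor samples, and a weighted Kolmogorov–Smirnov statistic asks
whether a pathway gene set (here, a 51-gene pyroptosis set) concentrates at
either end of that ranking. Walking the ordered list, set members increment
a running sum by $|r_i|^p / \sum_{\text{hits}} |r|^p$ and non-members
decrement it by $1/(N - N_h)$; the enrichment score (ES) is the signed value
of maximal absolute deviation, bounded in $[-1, 1]$.

Significance comes from a permutation null: the ES of `n_permutations`
random gene sets of the same size drawn from the ranked universe, with the
two-sided add-one p-value $p = (1 + \#\{|ES_0| \ge |ES|\})/(B + 1)$.
P-values are Benjamini–Hochberg adjusted across lncRNAs, and an lncRNA is
called pathway-coupled when $|ES| > 0.995$ and $q < 0.05$ (both strict).

Design choices made here, where the method description left them open:

* **Correlation**: Spearman by default, so this stage shares the pipeline's
  invariance to monotone *per-cohort* transforms (a per-gene rank statistic
  is unchanged when one increasing map is applied to a whole cohort).
  Pearson is available by flag. Note the distinction: the pair stages below
  are additionally invariant to *per-sample* warps, which do alter
  cross-sample correlations.
* **Weight exponent**: 1, the classical GSEA weighting.
* **Threshold scale**: the 0.995 cutoff is applied to the raw ES. A
  normalized enrichment score is not bounded by 1, so a threshold of 0.995
  is only meaningful on the raw statistic.
* **Null**: gene-set permutation rather than sample permutation — feasible
  per-lncRNA and matching the enrichment framework used.
* **Samples**: correlations use tumor samples only; mixing in normals would
  confound tumor-specific coupling with tissue composition.
* **Determinism**: each lncRNA gets a fixed permutation substream derived
  from the base seed and the lncRNA's position in the *sorted* id list, so
  results are independent of the row order of the input matrix.

## Stage 2: stable and reversal pairs

Expression is converted to within-sample ranks over the selected lncRNAs
(smallest value = rank 1; ties take the average rank). Then:

1. A pair is **stable** when one ordering holds in at least 85% of normal
   samples (inclusive bound — "in 85% of samples" includes 85%). Ties count
   toward neither ordering.
2. A stable pair is a **reversal** pair when the *opposite* ordering holds
   in at least 85% of tumor samples.
3. **Same-direction filter**: each gene's deregulation direction is the sign
   of the change in its median within-sample rank from normal to tumor;
   pairs whose members move in opposite directions (or not at all) are
   dropped.
4. **CV pruning**: for a pair, the per-tumor-sample rank difference
   $d_s = \mathrm{rank}_s(A) - \mathrm{rank}_s(B)$ measures how the pair
   relationship varies across individual tumors; its coefficient of
   variation $\mathrm{sd}(d)/|\overline{d}|$ (symmetric in A and B) ranks
   each gene's partners, and only the top 3 partners per gene are kept, a
   pair surviving when either member retains it. A zero mean gives
   CV = +Inf, i.e. maximal heterogeneity. The quantity whose CV is taken
   was not recoverable from the original description; the rank difference
   is our choice because it directly captures per-tumor heterogeneity of
   the pair relationship, and the statistic is pluggable.
5. **Qualification**: the tumor ordering must hold in strictly more than
   60% of tumor samples ("more than 60%" is read as a strict bound, unlike
   the inclusive 85% rules). With default thresholds this is implied by the
   reversal rule; both knobs stay independent because they are separate
   steps of the procedure.
6. **Encoding**: indicator 1 when expression of `gene_a` strictly exceeds
   `gene_b`, 0 otherwise (ties encode 0).

Pair sets from multiple cohorts are intersected requiring *identical tumor
orientation*; each cohort anchors its own stable pairs on its own normals,
and cross-cohort harmonization happens only at this intersection.

## Stage 3: the signature

Candidate pairs are screened by univariate Cox regression (Efron ties,
Wald tests): a pair must reach p < 0.05 in the training cohort and show a
hazard ratio on the same side of 1 in every cohort (an option demands
p < 0.05 everywhere; the looser reading is the default). Retained
indicators enter an L1-penalized Cox regression; the penalty path has 100
values spanning four decades below the smallest empty-model penalty, and
$\lambda$ is fixed at the minimum of the 10-fold cross-validated
partial-likelihood deviance, with folds stratified by event status and
seeded. Non-zero coefficients define the risk score
$\mathrm{score}(s) = \sum_i \beta_i x_{is}$ (no intercept).

Patients split at the cutoff maximizing the two-group log-rank statistic
over all admissible splits (midpoints of adjacent unique scores leaving at
least 10% of samples per side; ties resolve to the lower cutoff; no
multiplicity correction is applied to downstream log-rank p-values, a
documented limitation of the maximally-selected approach). Because a score
built from few binary indicators can concentrate nearly all mass on one
value, the search falls back to the best split with two non-empty groups
when no split meets the 10% floor, with a logged message. Group assignment
is strict: high risk means score *greater than* the cutoff. By default each
cohort re-estimates its own cutoff; a fixed-cutoff mode transfers the
training cutoff for stricter external validation.

## Stage 4: evaluation

* **Kaplan–Meier / log-rank** via the survival package.
* **Time-dependent AUC** (cumulative cases, dynamic controls) with inverse
  probability of censoring weights from the Kaplan–Meier estimate of the
  censoring distribution. This estimator reduces *exactly* to the binary
  Mann–Whitney AUC when no observation is censored before the horizon,
  which is what the oracle tests exploit; smoothed nearest-neighbor
  estimators would not have that property. Horizons use 1 year = 365.25
  days.
* **Harrell's C**: a pair of patients is usable when the shorter follow-up
  ended in an event (at tied times, when exactly one of the two had an
  event); concordant when that patient carries the higher score; tied
  scores count 1/2. The 95% CI is a seeded percentile bootstrap over
  samples (2000 draws by default).
* **Calibration**: a one-covariate Cox fit on the score gives per-sample
  predicted survival at a horizon (Breslow baseline); samples are binned
  into score tertiles (configurable) and mean predicted survival is
  compared with the Kaplan–Meier estimate per bin; bins emptied by ties
  merge with a neighbor.
* **Multivariate Cox** adjusts the score for clinical covariates
  (complete-case, collinearity rejected with the offending term named).
* **Two-group comparisons** for external per-sample quantities (mutation
  burden, immune scores, drug-response measures): Wilcoxon rank-sum for
  continuous values (exact for two groups of at most 50 without ties,
  normal approximation with continuity correction otherwise), Fisher's
  exact test for categorical ones. The external scores themselves are user
  inputs; computing them is out of scope.

## The synthetic multi-cohort generator

Real multi-cohort data with adjacent normals cannot ship with the package,
so every stage is exercised against a seeded generator with planted ground
truth (`simulate_cohorts()`). Its defaults are fixed at the study's
conditions — three cohorts of 348, 300 and 191 tumors (32/28/22 normals), a
51-gene pathway set — and the remaining scales were chosen once as values a
practitioner would call realistic for log2 expression units: baselines
uniform on [2, 14], gene-level noise SD 0.2, latent-factor loading 1.8 for
coupled genes, exponential event times with baseline rate 5e-4/day,
censoring calibrated analytically to a 40% target, log-hazard magnitudes
0.8–1.4.

The generative model: a per-sample latent pathway activity $z_s$ drives
both the pathway mRNAs and a subset of lncRNAs (so those lncRNAs' mRNA
correlation rankings place pathway genes at an extreme); all other genes are
independent noise around gene-specific baselines; each cohort passes through
its own strictly increasing transform (identity, affine, exponential) to
emulate platform differences; survival depends on the planted pair
indicators through a proportional-hazards model, the simplest law consistent
with the Cox stage it is meant to exercise.

**Why planted pairs are reversing blocks.** The obvious plant — swap the
baselines of two genes between normal and tumor — cannot survive the
pipeline's own Step-3 filter: if A overtakes B, A's rank moves up and B's
down, so the pair's members deregulate in opposite directions and the filter
discards the pair. More generally, any gene that lifts B's rank (so both
members can move "up") must itself drop below B, creating a reversal pair
with B — so exact recovery of the planted set *and* filter survival force
the lifters to be planted partners themselves. The resolution is a fully
reversing block: m lncRNAs occupy a private baseline window, ordered
$g_1 < \dots < g_m$ in normals and exactly reversed in tumors. All
$m(m-1)/2$ within-block pairs are then stable-and-reversal pairs, no pair
with an outside gene changes orientation (window privacy), and within a
4-block the rising half $(g_1, g_2)$ and the falling half $(g_3, g_4)$ each
form a same-direction pair that survives the full pipeline. Requested pair
counts compose from blocks of 4, 3 and 2; 2- and 3-blocks contribute
reversal pairs but no same-direction survivors (their members move in
opposite directions or not at all), which the recovery tests account for.

Member spacing (0.465 log2 units at noise SD 0.2) puts the per-sample
orientation probability of adjacent members near 0.95: comfortably above
the 0.85 support rules at the default normal-sample counts, while leaving a
~5% indicator minority so the Cox screen retains information. This mirrors
a structural feature of the real method: any pair passing an 85% reversal
rule necessarily has an imbalanced indicator, so risk-score granularity
comes from the number of pairs, not their balance.

What the generator deliberately does *not* model: probe-level rank noise
between platforms (cross-platform distortions are exactly monotone here),
correlated gene-gene noise beyond the single pathway factor, non-proportional
hazards, informative censoring, and realistic marginal distributions of any
particular platform. Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not robustness of the biology to
violations of it.

## Numerical and degenerate-input conventions

* Correlation ties in the mRNA ranking break lexicographically by gene id;
  ES running-sum ties resolve to the earliest position.
* If all hit weights are zero (all correlations exactly 0), hits fall back
  to equal weights.
* Zero-variance lncRNAs are an error in the correlation step; constant pair
  indicators are skipped with a warning in the Cox screen and excluded from
  cross-cohort consistency.
* Expression matrices must be NA-free: the rank logic has no missing-value
  semantics, and silent imputation would be worse than refusal.
* Cutpoint ties take the lower cutoff; score-equal-to-cutoff assigns "low".
* Every stochastic step (permutations, CV folds, bootstrap, simulation)
  draws from substreams derived arithmetically from one base seed, and
  restores the caller's RNG state afterwards.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the generator at reduced
but structurally faithful sizes (tens of lncRNAs, hundreds of mRNAs,
cohorts of 100–350 tumors, 199–500 permutations); the full-scale defaults
are a single function call away. Monte-Carlo checks fix their seeds, sizes
and replicate counts in the test code; the acceptance script reruns the
entire study-scale pipeline from one command-line seed.

## Known limitations

* The CV-pruning statistic is one defensible reading of an ambiguous
  procedure; alternatives (e.g. CV of the anchor's own rank) would change
  which pairs survive Step 4.
* The univariate screen's "p < 0.05 in three cohorts" is read as
  training-only significance plus direction consistency everywhere; the
  stricter reading is a configuration flag.
* The optimal-cutoff log-rank p-values are not corrected for the cutoff
  search.
* |ES| > 0.995 is extremely stringent on realistic data; with weaker
  coupling than the synthetic default, few or no lncRNAs may pass, which is
  a property of the published threshold, not of the implementation.
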