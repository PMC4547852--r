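---
title: "Methods: permutation-based epistasis detection in cancer alteration matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based epistasis detection in cancer alteration matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoepi)
```

## The problem and the null model

Tumors accumulate driver alterations — recurrent mutations, copy-number
gains and losses, promoter hypermethylation — and pairs of drivers that
appear together more or less often than expected point to cooperative or
partially redundant (epistatic) relationships. The statistical difficulty
is that tumors differ enormously in how many alterations they carry, and
alterations differ in how often they recur: any null model that ignores
either margin will call heavily-altered samples "co-occurring" and rare
alterations "mutually exclusive" for reasons that have nothing to do with
selection.

`oncoepi`'s null is the uniform distribution over binary matrices with
**both margins fixed**: per-sample loads and per-alteration recurrence
counts are preserved exactly, separately within every cancer-type ×
alteration-class block (mutation loads say nothing about copy-number
loads, and alteration frequencies differ between cancer types, so neither
may leak across blocks). Sampling is by attempted 2×2 checkerboard swaps:
two rows and two columns are drawn uniformly; if the induced submatrix is
diagonal or anti-diagonal it is flipped. The move is its own inverse and
the proposal is symmetric, so the chain is reversible with uniform
stationary distribution over the connected state space, which for this
move class is the full set of matrices with the given margins. An
important consequence: if the data-generating process is additive on the
logit scale (a sample effect plus an alteration effect — a Rasch-type
model), the conditional distribution of the matrix given its margins is
exactly uniform, so the test is exactly calibrated for arbitrary load
heterogeneity of that form.

## Tunable parameters

* `n_permutations` (default **10,000**): the resolution limit of an
  empirical P-value is 1/N; with Benjamini–Hochberg over hundreds of
  pairs, N = 1,000 cannot clear an FDR of 0.1 unless many pairs are true,
  which is why the default stays at 10,000 and down-scaled runs (e.g.
  saturation, default 1,000 per subset in our tests) are flagged as such.
* `burn_in` (default 10 × block nonzero count) and `thinning` (default
  the nonzero count), in **attempted** swaps per block, so chain cost is
  predictable regardless of acceptance rate. Two sampling modes exist:
  `"sequential"` (one long thinned chain; cheapest) and `"restart"`
  (every permutation is an independent burn-in from the observed matrix;
  draws are independent, which matters when a goodness-of-fit test will
  be applied to the samples themselves). Defaults were chosen for mixing
  on sparse driver matrices, where the nonzero count is a natural unit of
  chain work.
* `fdr` (default **0.1**, with 0.05 as the customary strict alternative)
  and `min_frequency` (default **0.02**): an alteration is testable in a
  scope if altered in at least `ceiling(0.02 × n)` of the samples under
  consideration, the ceiling guaranteeing that fractional counts never
  admit sub-threshold alterations.
* Hyper-altered exclusion: samples whose event count strictly exceeds
  Q3 + `multiplier` × IQR (default multiplier **4.5**) are dropped before
  testing. Quartiles use linear interpolation (R's type 7), recorded in
  the filter report; the rule can be applied globally (default — one
  threshold for the cohort) or per cancer type.

## Seeds and reproducibility

All permutation streams derive from one master seed: permutation *k* is a
pure function of `(seed, k)` via a per-segment substream seed, so a single
permutation can be regenerated without sweeping the stream, results do
not depend on evaluation order or batching, and every pair in a scope is
evaluated against the *same* permuted matrices (making pair statistics
comparable within a permutation, as when a whole matrix is permuted once
per iteration).

## Numerical choices

* **Ties.** Permuted co-occurrence values equal to the observed count are
  counted toward *both* one-sided P-values — the standard conservative
  convention for discrete statistics — so `P_co + P_me = 1 + P(tie)`.
* **Zero avoidance.** Empirical P-values are floored at 1/N; BH never
  receives a zero.
* **One- vs two-sided.** The BH adjustment is applied to
  `min(P_co, P_me)` without doubling; a `p_two = min(1, 2 p_min)` column
  is reported for users who want a two-sided-correct value.
* **Odds ratios.** Always continuity-corrected (+0.5 on every cell), so
  they are finite and positive; an empty table gives exactly 1. Logs are
  natural.
* **Tarone statistic.** The expected both-altered count under the
  Mantel–Haenszel common OR is the root of a quadratic inside
  `[max(0, m1+m2−n), min(m1, m2)]`; both roots are computed and the
  in-range one taken (the OR = 1 case is the linear limit `m1 m2 / n`).
  By default (+`correct = "auto"`) 0.5 is added to every cell of every
  stratum only when some cell is zero, keeping the statistic standard on
  well-populated tables; `"always"`/`"never"` force the choice, covering
  both plausible conventions for feeding corrected or raw counts to the
  heterogeneity test. Degenerate strata whose margins admit a single
  configuration carry no heterogeneity information and contribute zero.
  The differential empirical P uses the strict inequality
  `T_random > T_obs`; with discrete counts, exact ties at `T = 0` fall to
  the null side, which is conservative.
* **Direction calls.** The smaller one-sided P decides co-occurrence vs
  exclusivity; exact ties are broken by the odds ratio against 1.

## Design decisions where the design was open

* **BH scope of the differential screen** is the whole screen (all pair ×
  compared-type re-tests at once), not per detected type; the screen is
  one family of hypotheses and a single FDR statement about it is the
  interpretable one. Both non-redundant pair counts and total comparison
  counts are reported, since one pair may be re-tested against several
  types.
* **K = 2 strata per differential test** (detected vs one compared type):
  the question answered is "does this interaction differ between these
  two types"; a K > 2 omnibus variant exists in `tarone_statistic()` but
  the screen stays pairwise.
* **Whole-matrix permutation for the differential null**: the permuted
  datasets re-randomize both types' blocks with the engine's standard
  stratification, identical to the detection null.
* **Hyper-altered filtering is single-pass** (thresholds are not
  recomputed after exclusion) and precedes recurrence filtering.
* **Saturation subsets are nested within a replicate** (each size extends
  the previous draw), which reduces curve variance at no cost in
  unbiasedness of the per-size mean; recurrence filtering is recomputed
  inside every subset because the 2% rule refers to the samples under
  consideration. The final point of every curve reuses the analysis seed
  and therefore reproduces the non-subsampled run bit for bit.
* **Mann–Whitney is two-sided** (gains and losses are not
  sign-constrained), exact when both groups have ≤ 8 samples and no ties,
  normal approximation with tie correction otherwise; fully tied data are
  defined as no signal (p = 1). BH is per region, matching per-region
  gene ranking; a global option exists.
* **The enrichment resampling pool is alteration pairs** (not gene
  pairs), drawn uniformly without replacement among distinct eligible
  pairs, with the (+1)/(N+1) empirical-P estimator — the resample null is
  cheap and the statistic discrete, so the unbiased-at-zero estimator is
  preferable there.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws, per cancer type: planted pairs jointly from
the exact bivariate-Bernoulli cells matching their target odds ratio θ
(the quadratic construction in `joint_bernoulli_with_or()`, so manifest
ORs are analytic, not sampled); all other alterations independently at
logit(frequency) + u_s, with u_s ~ N(0, dispersion²) per sample
(default dispersion 0.4) and an extra +6 logit shift for a hyper-altered
fraction (default 2%) that the Q3 + 4.5 × IQR rule reliably separates on
the default 30-alteration panels. Load effects are applied only to
non-planted alterations so planted ORs stay exact; the deliberate price
is that at large n the asymmetry between load-carrying and planted
columns itself becomes a detectable (real, if weak) association among
background pairs — passing recovery tests therefore asserts that planted
pairs are found, not that nothing else is. The null-calibration cohort
plants nothing, so every column shares the sample effect, the Rasch
argument applies exactly, and the rejection rate of the one-sided
P-values is a meaningful calibration check. That check uses a panel of
highly recurrent alterations (frequencies 0.3–0.5): with rare
alterations the co-occurrence statistic is so discrete that the test is
visibly conservative (rejection well below α), which is a property of
tie-inclusive empirical P-values, not a miscalibration.

Not emulated: mutational signatures, subclonal structure, copy-number
segmentation, correlated alteration blocks beyond the planted pairs, or
the empirical frequency spectrum of real tumor cohorts. Conclusions
about real-data power or FDR must not be read off these cohorts.

## Problem sizes used in the shipped tests

Unit and acceptance tests run at deliberately modest scales chosen to
make their assertions sharp: margin conservation sweeps 1,000
permutations of the standard scenario (4 types × 300 samples, 30
alterations); sampler uniformity uses an exhaustively enumerated 4×4
state space at 10,000 independent-restart draws; empirical-P equivalence
a 5-sample toy against full enumeration; calibration two cohorts of 200
with 1,000 permutations; recovery 6 types × 300 (the extra types give
mutual-exclusivity, whose attainable P-values are bounded by the margins,
enough resolution at N = 1,000); the differential screen two cohorts of
400 with planted-pair frequency 0.2 (odds-ratio estimates at frequency
0.1 are too noisy for a stable Tarone signal at this n). The
`scripts/acceptance.R` report recomputes the same quantities end to end.

## Known limitations

* Empirical P-values inherit the discreteness of co-occurrence counts:
  for rare alterations the test is conservative, and no permutation count
  can fix that.
* The Breslow–Day/Tarone statistic is a two-stratum heterogeneity test;
  covariate-adjusted or model-based interaction contrasts are out of
  scope.
* The sequential chain's draws are autocorrelated; anything that treats
  permutations as independent samples (e.g. a goodness-of-fit test on
  the permutation stream itself) should use `mode = "restart"`.
* Analytic alternatives (Fisher/hypergeometric per pair) are deliberately
  absent: they answer a different question (fixed one margin, not both,
  and not stratified).
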