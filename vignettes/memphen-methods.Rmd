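---
title: "Methods: a generative recall model as a phenotyping engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a generative recall model as a phenotyping engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphen)
```

`memphen` turns a 30-word emotional free-recall task into eight
per-subject cognitive parameters and associates them with genotypes.
This vignette explains the model and its assumptions, the estimation
machinery, the synthetic-data generator that stands in for a real
cohort, and the numerical and design choices a maintainer should know
about.

## The generative model

The task presents six series of five nouns (ten each of neutral,
positive and negative valence, never more than three words of one
valence within a series) and scores free recall immediately after each
series and again, unexpectedly, after a five-minute delay. Behaviour is
summarised by eight performance measures: correct recalls per valence
and confabulative errors (responses not on the study list), at each
time point.

Each word receives a latent memory strength at encoding,
`m0 = eps_v * (alpha + N(0, sigma))`: learning rate `alpha` sets the
mean, `sigma` the encoding noise, and the valence multiplier `eps_v`
(`eps_pos`, `eps_neg`, or 1 for neutral) implements emotional
modulation of memory strength. Because the modulation multiplies the
whole strength, the law of `m0` is Normal with mean `eps_v * alpha`
*and* sd `eps_v * sigma`. An alternative reading — modulation of the
mean only, `m0 = eps_v * alpha + N(0, sigma)` — is available throughout
via `variant = "additive"`; the two variants are distinguishable only
through the higher moments of recall counts, and the multiplicative
form is the package default because modulation is described as acting
on the memory strength itself, noise included.

Recall is a two-stage decision. A word is *attempted* only if its
strength exceeds the decision threshold `beta` (strict inequality; the
tie set has measure zero). An attempted word is recalled correctly with
the logistic probability `g(m) = 1 / (1 + exp(-s (m - m50)))`, centred
at `m50 = 1`; an attempted-but-failed recall produces exactly one
confabulative error. This single mechanism generates all errors in the
model, and it reproduces the empirical trade-off in which low-threshold
subjects recall more words but also confabulate more. Words written
down at immediate recall have their strength multiplied by the
repetition improvement `c >= 1` (attempted-but-failed words get no
boost — only written words are rehearsed); the delay multiplies every
strength by the forgetting rate `gamma < 1`, after which the same
attempt/success rules apply to the delayed test.

The centre `m50 = 1` is a pure convention: multiplying `m50` by any
`k > 0` while scaling `alpha`, `beta`, `sigma` by `k` and `s` by `1/k`
leaves every observable unchanged. The test suite asserts this
invariance, which also explains why `alpha` and `beta` are only
interpretable relative to each other and to `sigma`.

Words are exchangeable given their valence: the model has no semantic
relatedness, no primacy/recency structure, and no arousal/valence
dissociation. Per-series recall is therefore equivalent to whole-list
recall, and the simulator tags series membership only so that generated
logs look like real ones.

## Exact expectations and the simulator

All fitting works on *expected* performance measures, computed per
valence as Gaussian integrals: `E[1(m0 > beta) g(m0)]` for immediate
correct recall, `P(m0 > beta)` minus that for immediate errors, and the
delayed analogues in which the integrand branches on whether the word
was recalled immediately (strength `gamma * c * m0`) or not
(`gamma * m0`). The integrands are piecewise smooth with kinks at
`beta`, `beta/gamma` and `beta/(gamma c)`, so the quadrature
(16-point Gauss–Legendre, compiled C++) splits the range
`[mu - 8 sd, mu + 8 sd]` at those points and doubles the panel count
per segment until successive estimates differ by less than 1e-7,
giving expected measures accurate to well below 1e-6 words; panel
doubling that fails to converge raises an error naming the parameter
set. The truncation at eight standard deviations discards Gaussian
mass below 1e-15.

A vectorised stochastic simulator implements the same process with
random draws. It serves two roles: as the independent oracle (averages
over 1e5 simulated sessions must agree with the quadrature to within
Monte-Carlo error — the suite checks 50 random parameter sets) and as
the synthetic-data engine producing integer performance measures and
raw recall logs.

## Estimation

Per subject, five free parameters are estimated and three are held at
population values (default partition: `alpha`, `beta`, `c`, `eps_pos`,
`eps_neg` free; `sigma`, `gamma`, `s` fixed). The objective is the
variance-weighted sum of squares
`chi2 = sum_i (PM_i_obs - PM_i_mod)^2 / var_i`, with `var_i` the
across-cohort variance of measure `i`, floored at 0.25 so that a
degenerate synthetic cohort cannot blow up the weights. The sum is not
divided by the number of measures, so `P(chi2, nu)` with
`nu = 8 - 5 = 3` applies directly; fits with `P > 0.05` are declared
adequate.

The search is deliberately derivative-free and reproducible:

1. **Grid.** Free parameters take values at odd-sixteenth fractions of
   their ranges (8 levels, 8^5 = 32768 points at full scale); ranges
   are `[0.3, 3.5]` for `alpha`, `beta`, `eps_pos`, `eps_neg`,
   `sigma`, `[1, 4.2]` for `c`, `(0, 0.8]` for `gamma`, `(0, 16]` for
   `s`.
2. **Hill climbing.** The ten best grid points (ties broken
   lexicographically so reruns are identical) seed first-improvement
   hill climbs with steps of 5% of each range, the candidate order
   drawn from a small Lehmer generator keyed by subject and start —
   deterministic, and independent of R's global RNG. End points are
   refined with 1% steps, and the component-wise average of the ten
   end points is also evaluated; the best point wins. The spread of
   the end points doubles as a reliability diagnostic
   (`summary()` of a fit prints it).
3. **Population stages.** Fixed parameters are estimated by scanning a
   4^3 grid (odd-eighth fractions), keeping the best candidates by
   cohort-mean chi-square, climbing them at 5% steps while individual
   parameters are held at their fitted values, and re-fitting the
   cohort under the winner (`estimate_fixed()`). `refine_fixed()`
   explores single 5% steps around the best sets, re-fitting the
   cohort at every step and expanding all improving steps
   breadth-first (capped at 32 live starts to bound cost);
   `combination_average()` then evaluates all `2^k - 1 <= 1023`
   subset averages of the ten best sets, which overcomes step-size
   granularity. `select_model()` ranks all `choose(8,3) = 56`
   free/fixed partitions by coarse cohort-mean chi-square and flags
   the top two for refinement. `run_estimation()` chains the stages;
   its reported cohort-mean chi-square is non-increasing by
   construction because stages two and three share one evaluator and
   always include their own starting points.
4. **Bootstrap.** `bootstrap_parameter_sets()` resamples one of each
   subject's ten stored end-point sets uniformly (10000 samples by
   default) so that any downstream statistic can be summarised by its
   median across samples, propagating estimation uncertainty.

Two presets size the machinery: `"paper"` (8^5 grid, 64 fixed sets,
all 56 models) is the full-scale procedure; `"desk"` (4^5 grid, 27
fixed sets, top 8 models) runs a subject fit in ~0.2 s and a
200-subject cohort in under a minute, and is what the test suite and
examples use. All enumeration counts are asserted against the
enumerators themselves, not against timed full runs.

The default fixed values are `sigma = 0.7`, `s = 4.133` — printed for
the closely competing second-best partition, whose fixed set shares
these two parameters — and `gamma = 0.5`, the midpoint of its range;
they are sensible defaults, not estimates, and every population-level
function re-estimates them.

## Phenotypes

`score_recall()` implements the scoring rule for typed responses: a
response matches a target if spelled exactly or within Levenshtein
distance 1, unless the distance-1 form is itself a different valid word
of the lexicon (study list plus an optional dictionary — the package
defaults to the study list because no reference dictionary is bundled).
Transpositions count as two edits and fail by default
(`transpositions = TRUE` switches to Damerau-style scoring); each
target matches at most once; unmatched responses are confabulative
errors. `compute_performance_measures()` applies the rule per series
(immediate) and against the whole list (delayed).

`emotional_contrast()` computes classical valence contrasts such as the
negative-minus-neutral proportion recalled, the picture-task phenotype
most closely related to `eps_neg`. `pca_performance()` performs
correlation-matrix PCA of the eight measures — they mix counts and
error tallies on different scales, so z-scoring is the defensible
choice; a variance floor with a warning handles near-constant columns.
`normality_screen()` is a Lilliefors-type test (KS statistic with
estimated mean and sd) whose null distribution is simulated (10^4
seeded resamples) rather than read from tables, exact at any n; a
p-value below 0.05 recommends rank-based association, which is why the
association layer is Spearman throughout.

## Association

Markers are filtered on call rate (≥ 0.95), minor allele frequency
(≥ 0.05) and Hardy–Weinberg equilibrium (Pearson χ², 1 df, p ≥ 0.05);
the three rules commute, so filtering is order-independent and
idempotent. The additive model correlates the phenotype with the
effect-allele count (0/1/2) by Spearman rank correlation with average
ranks and the t-approximation for p (`stats::cor.test`,
`exact = FALSE`) — with hundreds of tied genotype ranks an exact null
is impractical, and the suite verifies the approximation's type-I
error against a 2000-draw permutation null at n = 300. Missing
dosages are dropped pairwise; no imputation. Bonferroni correction
uses the post-QC marker count. `subsample_consistency()` re-runs the
association per recruitment site and pooled (simple pooling, with
per-site reporting, is the default for multi-site cohorts).

## The synthetic cohort

`cohort_spec()` defaults describe the study conditions the package is
calibrated to: 1239 subjects; a causal marker with genotype groups of
exactly 137, 532 and 570 carriers of two, one and zero effect alleles
(HWE binomial sampling is used for other cohort sizes, at the implied
allele frequency 0.325); per-genotype `eps_neg` means 1.20, 1.14, 1.08
with a common within-group sd of 0.23 (the reported group standard
errors times the square roots of the group sizes are all ≈ 0.23, which
is why one shared sd suffices); and background laws for the other free
parameters centred on the fitted cohort means (`alpha` 1.93, `beta`
1.27, `c` 1.95, `eps_pos` 1.09). The background sds (0.45, 0.35, 0.5,
0.2 respectively) are not reported quantities; they were chosen once as
plausible inter-individual spreads — wide enough that recovery is
non-trivial, narrow enough that most subjects stay well inside the
search ranges — and are not tuned. All parameter draws are normals
truncated to the search ranges by rejection; a truncation retaining
less than 1e-6 of the mass is an error.

Seeding is hierarchical: a master seed spawns per-stage and per-subject
children through a counter-based map, so any single subject's session
can be regenerated in isolation. Generated recall logs round-trip
exactly through the scoring rule: correct recalls are written as the
exact study words, confabulations as short tokens kept at edit distance
greater than one from every study word.

What the generator does *not* emulate: linkage disequilibrium,
polygenic architecture, covariates (age, sex, site effects on the
phenotype), semantic structure in the word lists, and any
subject-level variation in the population-fixed parameters. Passing
tests on these cohorts therefore demonstrate the correctness of the
machinery and the statistical calibration of the generator — not that
the model captures all structure of real recall data.

## Numerical choices and degenerate inputs

* Quadrature: absolute tolerance 1e-7 at panel doubling, range
  ±8 sd, explicit splits at the three indicator kinks; convergence
  failure is an error, never a silent result.
* Ties: grid ties broken lexicographically; attempt ties (`m = beta`)
  resolved as no attempt; average ranks for Spearman.
* Floors: PM variance floor 0.25; PCA variance floor 1e-12 (with
  warning); monomorphic markers get HWE p = 1 with a warning;
  constant phenotypes yield a flagged null association rather than an
  error.
* Determinism: every stochastic component (simulator, hill-climb
  ordering, generator, bootstrap, Monte-Carlo nulls) takes an explicit
  seed; the hill-climb ordering uses its own Lehmer stream so package
  code never perturbs the caller's RNG state.

## Known limitations

* The `eps_neg` recovery from a single 30-word session is noisy: with
  the calibrated genotype effect, the rank correlation between true
  and fitted `eps_neg` is about 0.45 at desk scale, which attenuates
  the fitted-phenotype association by the same factor. Detecting the
  calibrated effect on *fitted* parameters therefore needs cohorts in
  the hundreds-to-thousands, which is why the generator's default
  cohort size is 1239; the test
  suite asserts the direction of the fitted-phenotype association and
  reserves effect-size checks for the true parameters, where the
  calibration is exact.
* The fixed-parameter landscape is shallow: quite different
  `(sigma, gamma, s)` triples fit a cohort almost equally well
  (forgetting and repetition improvement trade off against each
  other), so fixed-parameter recovery is only meaningful to within a
  hill-climbing step, and model selection between the top partitions
  rests on small chi-square differences.
* Config files are YAML or JSON; TOML is not supported.
* The association layer deliberately omits population-stratification
  correction, imputation and mixed models; it is a phenotyping
  pipeline, not a GWAS toolkit.
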