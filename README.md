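# memphen

Model-based phenotyping of emotional verbal memory for genetic
association studies.

Free-recall performance is the joint outcome of several cognitive
processes — encoding, forgetting, emotional modulation of memory
strength, and the decision strategy for weakly remembered items — and
raw recall counts confound them all. `memphen` implements a generative
computational model of a 30-word emotional free-recall task (ten
neutral, ten positive, ten negative nouns, recalled immediately and
after a 5-minute delay) that dissociates these processes into eight
interpretable parameters, fits the model to each subject's eight
performance measures by χ² minimisation, and uses the fitted
parameters — above all the negative emotional modulation ε_neg — as
quantitative phenotypes for SNP association under an additive genetic
model. A synthetic-cohort generator makes the whole pipeline runnable
and testable without any external data.

It is written for quantitative researchers in behavioural genetics and
computational psychiatry who want latent cognitive parameters, rather
than raw test scores, as GWAS phenotypes.

## The model

Each studied word receives a latent memory strength at encoding

    m0 = ε_v · (α + N(0, σ)),

where α is the learning rate, σ the encoding-noise standard deviation,
and ε_v the emotional modulation (ε_pos for positive, ε_neg for
negative, 1 for neutral words). A word is attempted in free recall only
if its strength exceeds the decision threshold β; an attempted word is
recalled correctly with the logistic probability

    g(m) = 1 / (1 + exp(−s · (m − m_50%))),     m_50% = 1,

and an attempted-but-failed recall produces one confabulative error.
Words written down at immediate recall have their strength multiplied
by the repetition improvement c (≥ 1); the 5-minute delay multiplies
all strengths by the forgetting rate γ (< 1), after which the same
attempt/success rules apply. The eight performance measures PM₁–PM₈
(correct recalls per valence and errors, at the two time points) have
closed-form expectations as Gaussian integrals, which the package
evaluates by adaptive Gauss–Legendre quadrature (a stochastic simulator
provides the independent control).

Per subject, five parameters (α, β, c, ε_pos, ε_neg by default) are
free and three (σ, γ, s) are population-fixed; the fit minimises

    χ² = Σᵢ (PMᵢ_obs − PMᵢ_mod)² / (σᵢ_exp)²

over a regular grid (8⁵ points at full scale) followed by seeded
deterministic hill climbing, with P(χ², ν = 3) > 0.05 declaring an
adequate fit. Population stages estimate the fixed parameters, rank all
56 free/fixed partitions, average combinations of the best fixed sets,
and bootstrap over each subject's ten hill-climbing end points.
Association uses marker QC (call rate ≥ 0.95, MAF ≥ 0.05, HWE p ≥
0.05), Spearman rank correlation against allele dosage, and Bonferroni
correction.

## Worked example

```r
library(memphen)
spec <- cohort_spec(seed = 7)       # 1239 subjects, calibrated genotype effect
cohort <- generate_cohort(spec)
cohort
#> Synthetic cohort: 1239 subjects, 21 markers, 54914 log rows

# fit the recall model to the first subject's performance measures
disp <- pm_dispersion(cohort$pm_table)
fit <- fit_recall(cohort$pm_table[1, ], dispersion = disp)
fit
#> Recall-model fit (chi-square)
#>   chi2 = 0.7608 on nu = 3, P(chi2, nu) = 0.859 (adequate)
#>   free: alpha, beta, c, eps_pos, eps_neg
#>   alpha    beta   gamma eps_pos eps_neg   sigma       c       s
#>  2.1464  1.3016  0.5000  0.9688  1.0520  0.7000  1.5472  4.1330
round(fitted(fit), 2)
#>  pm1  pm2  pm3  pm4  pm5  pm6  pm7  pm8
#> 8.49 8.82 8.63 0.70 6.72 7.40 7.00 1.17

# marker QC, then association of the negative-modulation phenotype
qc <- qc_filter(cohort$genotypes)
associate_marker(cohort$truth$parameters$eps_neg,
                 cohort$genotypes$dosage[, "causal"],
                 marker_id = "causal",
                 n_tests = ncol(qc$genotypes$dosage))
#> causal: rho = 0.159, P_nominal = 1.71e-08, P_Bonferroni = 3.58e-07 (n = 1239)
#>  dosage   n     mean         sem
#>       0 570 1.076068 0.009410451
#>       1 532 1.122118 0.009440453
#>       2 137 1.207301 0.020747527
```

The subject fit says the model reproduces this subject's eight recall
counts to within cohort noise (P = 0.86); the association table shows
the per-genotype means of ε_neg rising with the effect-allele count and
a Spearman ρ of 0.159 with genome-wide-significant nominal p.

A thin command-line wrapper with the same functionality is installed at
`inst/cli/memphen` (subcommands `simulate`, `fit`, `select-model`,
`pca`, `assoc`, `report`).

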