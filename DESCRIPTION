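Package: memphen
Title: Model-Based Phenotyping of Emotional Verbal Memory for Genetic
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative computational model of a verbal free-recall task
    with emotional (positive, negative, neutral) word material: latent
    memory-strength dynamics with encoding noise, emotional modulation,
    repetition improvement and forgetting; exact expected performance
    measures by numerical quadrature with a stochastic simulator as
    control; chi-square goodness-of-fit estimation of per-subject
    cognitive parameters by grid search and deterministic hill climbing,
    with population-level fixed-parameter estimation, 5-of-8 model
    selection, combination averaging and bootstrap over hill-climbing
    end points; derived model-based phenotypes (notably negative
    emotional modulation of memory strength) with marker quality
    control (call rate, minor allele frequency, Hardy-Weinberg
    equilibrium) and Spearman rank association under an additive
    genetic model with Bonferroni correction; and a synthetic-cohort
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest
Config/testthat/edition: 3
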