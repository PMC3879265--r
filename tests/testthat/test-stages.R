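# population-level estimation stages, model selection, bootstrap

test_that("fixed parameters are recovered on a noise-free cohort", {
  set.seed(3)
  sp <- model_spec()
  truth_fixed <- c(gamma = range_fraction("gamma", 3 / 6),
                   sigma = range_fraction("sigma", 1 / 6),
                   s = range_fraction("s", 1 / 6))
  n <- 8
  free <- cbind(alpha = runif(n, 1.2, 2.6), beta = runif(n, 0.8, 1.8),
                c = runif(n, 1.3, 2.8), eps_pos = runif(n, 0.9, 1.3),
                eps_neg = runif(n, 0.9, 1.4))
  tab <- exact_pm_cohort(n, free, truth_fixed, sp)
  cfg <- fit_config("desk", free_levels = 3, n_starts = 3,
                    n_keep_fixed = 2, fixed_levels = 3)
  ef <- estimate_fixed(tab, sp, cfg)
  r <- param_ranges()[names(ef$fixed_values), ]
  step <- 0.05 * (r$upper - r$lower)
  err <- abs(ef$fixed_values - truth_fixed[names(ef$fixed_values)])
  expect_true(all(err <= step + 1e-9))
  # reported cohort mean equals the arithmetic mean of subject chi2
  expect_equal(ef$mean_chi2, mean(ef$cohort_fit$parameters$chi2))
})

test_that("fixed-candidate ranking is invariant to subject order", {
  set.seed(11)
  sp <- model_spec()
  n <- 5
  free <- cbind(alpha = runif(n, 1.2, 2.4), beta = runif(n, 0.9, 1.6),
                c = runif(n, 1.3, 2.5), eps_pos = runif(n, 0.95, 1.25),
                eps_neg = runif(n, 0.95, 1.35))
  tab <- exact_pm_cohort(n, free, c(sigma = 0.7, gamma = 0.5, s = 4.133),
                         sp)
  cfg <- fit_config("desk", free_levels = 2, n_starts = 2,
                    n_keep_fixed = 1, fixed_levels = 2)
  a <- estimate_fixed(tab, sp, cfg)
  b <- estimate_fixed(tab[n:1, ], sp, cfg)
  expect_equal(a$candidates$mean_chi2, b$candidates$mean_chi2,
               tolerance = 1e-10)
  expect_equal(a$fixed_values, b$fixed_values)
})

test_that("model selection enumerates and ranks all 56 partitions", {
  specs <- enumerate_model_specs()
  expect_length(specs, 56)
  for (sp in specs) {
    expect_length(intersect(sp$free, sp$fixed), 0)
    expect_setequal(c(sp$free, sp$fixed), param_names())
  }
  # with a mocked evaluator the argmin partition is ranked first
  target <- "gamma,sigma,s"
  fake <- function(sp) {
    if (paste(sp$fixed, collapse = ",") == target) 0.5 else 2 +
      sum(utf8ToInt(paste(sp$fixed, collapse = ""))) / 1000
  }
  sel <- select_model(NULL, evaluate = fake)
  expect_equal(sel$fixed[1], target)
  expect_equal(sel$mean_chi2[1], 0.5)
  expect_true(all(sel$refine[1:2]))
  expect_equal(sum(sel$refine), 2)
  expect_true(!is.unsorted(sel$mean_chi2))
})

test_that("combination averaging scans every non-empty subset", {
  sets <- matrix(runif(30), 10, 3,
                 dimnames = list(NULL, c("sigma", "gamma", "s")))
  calls <- 0
  res <- combination_average(sets, function(fv) {
    calls <<- calls + 1
    sum(fv)
  })
  expect_equal(res$n_subsets, 1023)
  expect_equal(calls, 1023)
  # minimising the sum picks the subset of the smallest column sums
  expect_equal(res$best_chi2, min(res$table$mean_chi2))
  # singleton input comes back unchanged
  one <- combination_average(sets[1, , drop = FALSE],
                             function(fv) sum(fv))
  expect_equal(one$n_subsets, 1)
  expect_equal(unname(one$best_fixed), unname(sets[1, ]))
  # identical inputs make every average identical
  same <- combination_average(sets[rep(1, 4), ], function(fv) sum(fv))
  expect_equal(diff(range(same$table$mean_chi2)), 0)
})

test_that("stage-2 refinement only improves the cohort fit", {
  set.seed(21)
  sp <- model_spec()
  n <- 4
  free <- cbind(alpha = runif(n, 1.3, 2.2), beta = runif(n, 0.9, 1.5),
                c = runif(n, 1.4, 2.2), eps_pos = runif(n, 1.0, 1.2),
                eps_neg = runif(n, 1.0, 1.3))
  tab <- exact_pm_cohort(n, free, c(sigma = 0.7, gamma = 0.5, s = 4.133),
                         sp)
  cfg <- fit_config("desk", free_levels = 2, n_starts = 2,
                    n_keep_fixed = 1, fixed_levels = 2,
                    max_live_starts = 4)
  start <- matrix(c(0.5, 1.9, 8), 1,
                  dimnames = list(NULL, c("gamma", "sigma", "s")))
  ref <- refine_fixed(tab, sp, start, cfg)
  expect_lte(ref$best_chi2, ref$evaluated$mean_chi2[
    nrow(ref$evaluated)])
  expect_true(!is.unsorted(ref$evaluated$mean_chi2))
  # full pipeline: cohort-mean chi2 never increases across stages
  pipe <- run_estimation(tab, sp, cfg)
  expect_lte(pipe$stage2$mean_chi2, pipe$stage1$mean_chi2 + 1e-9)
  expect_lte(pipe$stage3$mean_chi2, pipe$stage2$mean_chi2 + 1e-9)
})

test_that("bootstrap draws one stored set per subject, reproducibly", {
  sets <- lapply(1:5, function(i) {
    m <- as.data.frame(matrix(rep(seq(0.5, 1.1, 0.2), each = 8),
                              4, 8, byrow = TRUE))
    names(m) <- param_names()
    m + i / 10
  })
  bs <- bootstrap_parameter_sets(sets, n_samples = 50, seed = 8)
  expect_equal(bs$n_samples, 50)
  expect_equal(dim(bs$index), c(50L, 5L))
  expect_true(all(bs$index >= 1 & bs$index <= 4))
  d1 <- bs$draw(3)
  expect_equal(dim(d1), c(5L, 8L))
  bs2 <- bootstrap_parameter_sets(sets, n_samples = 50, seed = 8)
  expect_identical(bs$index, bs2$index)
  # default sample count follows the bootstrap protocol
  expect_equal(formals(bootstrap_parameter_sets)$n_samples, 10000)
  # degenerate case: identical stored sets per subject
  same <- lapply(1:4, function(i) {
    m <- as.data.frame(matrix(1.2, 3, 8))
    names(m) <- param_names()
    m
  })
  bsd <- bootstrap_parameter_sets(same, n_samples = 20, seed = 2)
  stat <- function(par) mean(par[, "eps_neg"])
  out <- bootstrap_summary(bsd, stat)
  expect_equal(unique(out$values), 1.2)
  expect_equal(out$median, 1.2)
})
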