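# scoring rule, PM construction, contrasts, PCA, normality screen

test_that("recall scoring accepts single typos unless they form words", {
  targets <- c("poverty", "angle", "happiness")
  # exact spelling
  expect_equal(score_recall(targets, "poverty"), 1L)
  # one inserted letter, not a valid word
  expect_equal(score_recall(targets, "anglee"), 2L)
  # a typo that lands on a different valid word is an error
  expect_true(is.na(score_recall(targets, "ankle",
                                 lexicon = c("ankle", "house"))))
  # without that word in the lexicon the same response matches
  expect_equal(score_recall(targets, "ankle"), 2L)
  # unmatched responses are confabulative errors
  expect_true(is.na(score_recall(targets, "zebra")))
  # each target is matched at most once
  m <- score_recall(targets, c("angle", "angle"))
  expect_equal(m[1], 2L)
  expect_true(is.na(m[2]))
  # transpositions are distance 2 by default but allowed when asked
  expect_true(is.na(score_recall(targets, "nagle")))
  expect_equal(score_recall(targets, "nagle", transpositions = TRUE), 2L)
})

test_that("scoring is stable under response and list order", {
  targets <- c("poverty", "angle", "happiness", "window")
  resp <- c("window", "powerty", "zzz", "angle")
  m <- score_recall(targets, resp)
  n_match <- sum(!is.na(m))
  expect_lte(n_match, length(targets))
  for (i in 1:5) {
    perm <- sample(seq_along(resp))
    expect_equal(sum(!is.na(score_recall(targets, resp[perm]))), n_match)
    permt <- sample(seq_along(targets))
    expect_equal(sum(!is.na(score_recall(targets[permt], resp))), n_match)
  }
})

test_that("performance measures tally matches and errors per phase", {
  d <- task_design()
  sl <- memphen:::synthetic_study_list(d)
  # perfect recall in both phases
  resp_imm <- data.frame(subject_id = "a", phase = "immediate",
                         series = sl$series, response = sl$word)
  resp_del <- data.frame(subject_id = "a", phase = "delayed",
                         series = NA, response = sl$word)
  pm <- compute_performance_measures(sl, rbind(resp_imm, resp_del), d)
  expect_equal(unname(pm), c(10, 10, 10, 0, 10, 10, 10, 0))
  # no responses at all
  empty <- resp_imm[0, ]
  expect_equal(unname(compute_performance_measures(sl, empty, d)),
               rep(0, 8))
  # malformed phase is reported with its row
  bad <- resp_imm
  bad$phase[3] <- "later"
  expect_error(compute_performance_measures(sl, bad, d), "row 3")
})

test_that("simulated logs reproduce the simulator's PM vector", {
  spec <- cohort_spec(n_subjects = 4, seed = 19, n_null_markers = 0)
  coh <- generate_cohort(spec)
  for (i in 1:4) {
    id <- coh$pm_table$subject_id[i]
    pm <- compute_performance_measures(
      coh$study_list, coh$logs[coh$logs$subject_id == id, ], coh$design)
    expect_equal(unname(pm), unname(unlist(coh$pm_table[i, pm_names()])),
                 info = id)
  }
})

test_that("emotional contrast is the difference in recall", {
  expect_equal(emotional_contrast(c(negative = 0.443, neutral = 0.280)),
               0.163)
  expect_equal(emotional_contrast(c(negative = 0.490, neutral = 0.293)),
               0.197)
  expect_equal(emotional_contrast(c(negative = 0.3, neutral = 0.3)), 0)
  expect_error(emotional_contrast(c(negative = 0.3), "negative",
                                  "neutral"), "present")
})

test_that("PM principal components behave like correlation-matrix PCA", {
  set.seed(31)
  # rank-1 structure: one component carries all the variance
  u <- rnorm(40)
  tab1 <- as.data.frame(outer(u, seq(1, 2.4, 0.2)))
  names(tab1) <- pm_names()
  p1 <- pca_performance(tab1)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-10)
  # variance fractions always complete to 1, loadings orthonormal
  tab <- as.data.frame(matrix(rnorm(8 * 500), 500, 8))
  names(tab) <- pm_names()
  p <- pca_performance(tab)
  expect_equal(sum(p$variance_fraction), 1)
  expect_equal(crossprod(p$loadings), diag(8), ignore_attr = TRUE,
               tolerance = 1e-10)
  # isotropic data: every component near 1/8
  expect_true(all(abs(p$variance_fraction - 1 / 8) < 0.03))
  # constant column triggers the variance floor, not a crash
  tabc <- tab
  tabc$pm8 <- 2
  expect_warning(pca_performance(tabc), "variance floor")
})

test_that("normality screen calibrates under the null and has power", {
  # Gaussian null: rejection rate near the nominal 5%
  set.seed(13)
  rejections <- mean(replicate(120, {
    normality_screen(rnorm(50), n_mc = 120, seed = 99)$p_value < 0.05
  }))
  expect_lt(abs(rejections - 0.05), 0.05)
  # strong bimodality is detected
  x <- c(rep(0, 30), rep(1, 30)) + rnorm(60, 0, 1e-4)
  out <- normality_screen(x, n_mc = 2000, seed = 5)
  expect_lt(out$p_value, 0.001)
  expect_equal(out$recommendation, "spearman")
  expect_error(normality_screen(rnorm(10)), "at least 20")
})

test_that("the Lilliefors statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(17)
  for (x in list(rnorm(35), rexp(60), runif(100))) {
    expect_equal(memphen:::lilliefors_statistic(x),
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})
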