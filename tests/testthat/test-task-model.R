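# generative task model: sigmoid, encoding law, exact expectations,
# stochastic simulator

test_that("recall probability is the logistic curve in memory strength", {
  expect_equal(recall_probability(1, s = 4.133, m50 = 1), 0.5)
  expect_equal(recall_probability(1 + log(3) / 2, s = 2, m50 = 1), 0.75)
  expect_equal(recall_probability(1e3, s = 1), 1)
  expect_equal(recall_probability(-1e3, s = 1), 0)
  m <- seq(-2, 4, by = 0.1)
  expect_true(all(diff(recall_probability(m, s = 3)) > 0))
  expect_error(recall_probability(1, s = 0), "positive")
  expect_error(recall_probability(1, s = 1, m50 = -1), "positive")
})

test_that("encoding law scales mean and sd by the emotional modulation", {
  p <- recall_params(alpha = 1.93, sigma = 0.7)
  neu <- encoding_distribution(p, "neutral")
  expect_equal(neu$mean, 1.93)
  expect_equal(neu$sd, 0.7)
  p2 <- recall_params(alpha = 2, sigma = 0.5, eps_neg = 1.5)
  neg <- encoding_distribution(p2, "negative")
  expect_equal(neg$mean, 3.0)
  expect_equal(neg$sd, 0.75)
  # eps = 1 makes an emotional law identical to the neutral one
  p3 <- recall_params(eps_pos = 1)
  expect_equal(encoding_distribution(p3, "positive"),
               encoding_distribution(p3, "neutral"))
  # additive variant leaves the noise unscaled
  add <- encoding_distribution(p2, "negative", variant = "additive")
  expect_equal(add$mean, 3.0)
  expect_equal(add$sd, 0.5)
})

test_that("expected PMs match a Monte-Carlo oracle on random parameters", {
  set.seed(42)
  for (i in 1:6) {
    th <- random_params()
    e <- expected_pm(th)
    mc <- mc_expected_pm(th, n_sim = 2e4, seed = i)
    expect_true(all(abs(e - mc$mean) <= pmax(3 * mc$se, 1e-3)),
                info = paste("set", i))
  }
})

test_that("near-deterministic encoding saturates neutral recall", {
  th <- recall_params(alpha = 1.5, beta = 1.27, sigma = 0.01, s = 16,
                      eps_pos = 1, eps_neg = 1, enforce_ranges = FALSE)
  e <- expected_pm(th)
  expect_equal(unname(e["pm3"]), 9.9966, tolerance = 1e-3)
})

test_that("no delay change when c = 1 and gamma -> 1", {
  th <- recall_params(c = 1, gamma = 1 - 1e-9, enforce_ranges = FALSE)
  e <- expected_pm(th)
  expect_equal(unname(e[5:7]), unname(e[1:3]), tolerance = 1e-5)
  expect_equal(unname(e["pm8"]), unname(e["pm4"]), tolerance = 1e-5)
})

test_that("threshold at the range maximum suppresses all recall", {
  th <- recall_params(alpha = 0.3, beta = 3.5, sigma = 0.3,
                      eps_pos = 1, eps_neg = 1)
  expect_true(all(expected_pm(th) < 1e-3))
  sim <- simulate_subject(th, seed = 1)
  expect_true(all(sim$pm == 0))
})

test_that("rescaling m50 with alpha, beta, sigma and 1/s is equivalent", {
  th <- recall_params()
  k <- 2.5
  th2 <- recall_params(alpha = k * th["alpha"], beta = k * th["beta"],
                       sigma = k * th["sigma"], s = th["s"] / k,
                       gamma = th["gamma"], c = th["c"],
                       eps_pos = th["eps_pos"], eps_neg = th["eps_neg"],
                       enforce_ranges = FALSE)
  d2 <- task_design(m50 = k)
  expect_equal(expected_pm(th), expected_pm(th2, d2), tolerance = 1e-6)
})

test_that("expected PMs move monotonically with the cognitive parameters", {
  base <- recall_params()
  pm_at <- function(...) expected_pm(recall_params(...))
  # learning rate raises immediate recall
  alphas <- seq(0.5, 3.0, length.out = 6)
  imm <- sapply(alphas, function(a) pm_at(alpha = a)[1:3])
  expect_true(all(diff(t(imm)) > -1e-8))
  # threshold lowers both attempts and immediate errors
  betas <- seq(0.5, 3.0, length.out = 6)
  err <- sapply(betas, function(b) pm_at(beta = b)["pm4"])
  expect_true(all(diff(err) < 1e-8))
  # negative modulation raises delayed negative recall, leaves
  # neutral recall untouched
  es <- seq(0.8, 2.0, length.out = 5)
  mat <- sapply(es, function(e) pm_at(eps_neg = e)[c("pm6", "pm3", "pm7")])
  expect_true(all(diff(mat["pm6", ]) > -1e-8))
  expect_equal(diff(mat["pm3", ]), rep(0, 4), tolerance = 1e-8)
  expect_equal(diff(mat["pm7", ]), rep(0, 4), tolerance = 1e-8)
  # less forgetting and a stronger repetition boost help delayed recall
  gs <- seq(0.2, 0.8, length.out = 5)
  del <- sapply(gs, function(g) sum(pm_at(gamma = g)[5:7]))
  expect_true(all(diff(del) > -1e-8))
  cs <- seq(1, 4, length.out = 5)
  del_c <- sapply(cs, function(cc) sum(pm_at(c = cc)[5:7]))
  expect_true(all(diff(del_c) > -1e-8))
})

test_that("per-word outcomes conserve probability and attempts", {
  sim <- simulate_subject(recall_params(), seed = 7)
  tr <- sim$traces
  # attempted words are exactly the recalled-or-errored ones
  expect_equal(tr$m0 > recall_params()["beta"],
               tr$recalled_immediate | tr$errored_immediate,
               ignore_attr = TRUE)
  expect_false(any(tr$recalled_immediate & tr$errored_immediate))
  expect_false(any(tr$recalled_delayed & tr$errored_delayed))
  # delayed strength follows the boost/forgetting rule
  p <- recall_params()
  expect_equal(tr$m_delayed,
               p[["gamma"]] * tr$m0 * ifelse(tr$recalled_immediate,
                                             p[["c"]], 1))
})

test_that("the simulator is reproducible and respects the design", {
  p <- recall_params()
  a <- simulate_subject(p, seed = 123)
  b <- simulate_subject(p, seed = 123)
  expect_identical(a, b)
  d <- task_design()
  expect_equal(nrow(a$traces), sum(d$n_per_valence))
  counts <- table(a$traces$series, a$traces$valence)
  expect_true(all(counts <= d$max_per_valence_per_series))
  expect_equal(unname(colSums(counts)[c("neutral", "positive", "negative")]),
               unname(d$n_per_valence))
})

test_that("parameter containers validate ranges and structure", {
  expect_error(recall_params(alpha = 5), "outside")
  expect_silent(recall_params(alpha = 5, enforce_ranges = FALSE))
  expect_error(recall_params(gamma = -0.1), "positive")
  expect_error(model_spec(free = c("alpha", "beta", "c", "eps_pos")),
               "5 distinct")
  expect_error(model_spec(fixed_values = c(sigma = 0.7, gamma = 0.5,
                                           c = 2)),
               "named exactly")
  expect_error(task_design(n_per_valence = c(neutral = 12, positive = 10,
                                             negative = 10)),
               "total word count")
})
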