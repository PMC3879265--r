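# marker QC, HWE, Spearman association, Bonferroni, summaries

test_that("HWE test reproduces textbook and reported p-values", {
  expect_equal(hwe_test(c(25, 50, 25)), 1)
  expect_equal(hwe_test(c(63, 93, 37)), 0.8, tolerance = 0.01)
  expect_lt(hwe_test(c(50, 0, 50)), 1e-10)
  expect_warning(p <- hwe_test(c(100, 0, 0)), "monomorphic")
  expect_equal(p, 1)
  expect_error(hwe_test(c(1, 2)), "hom_ref")
})

test_that("QC drops markers by call rate, MAF and HWE with reasons", {
  set.seed(41)
  n <- 400
  good <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  low_maf <- rbinom(n, 2, 0.04)
  low_call <- good
  low_call[sample(n, 30)] <- NA       # call rate 0.925
  bad_hwe <- c(rep(0, 200), rep(2, 200))
  d <- cbind(good = good, low_maf = low_maf, low_call = low_call,
             bad_hwe = bad_hwe)
  rownames(d) <- paste0("s", 1:n)
  qc <- qc_filter(genotype_matrix(d))
  rep_ <- qc$report
  expect_true(rep_$keep[rep_$marker_id == "good"])
  expect_match(rep_$reasons[rep_$marker_id == "low_maf"], "maf")
  expect_match(rep_$reasons[rep_$marker_id == "low_call"], "call_rate")
  expect_match(rep_$reasons[rep_$marker_id == "bad_hwe"], "hwe")
  expect_equal(colnames(qc$genotypes$dosage), "good")
  # idempotent on the retained set
  qc2 <- qc_filter(qc$genotypes)
  expect_equal(colnames(qc2$genotypes$dosage),
               colnames(qc$genotypes$dosage))
})

test_that("Spearman association uses average ranks with t-approximation", {
  # a phenotype that is a monotone function of dosage (sharing its
  # tie pattern) gives rho = 1 under average ranks
  g <- rep(0:2, each = 5)
  sp <- spearman_association(2 * g + 1, g)
  expect_equal(sp$rho, 1)
  # brute-force rank formula as oracle on a tied worked example
  gg <- rep(c(0, 1, 2, 0, 1), 2)
  yy <- rep(c(0.9, 1.1, 1.3, 1.0, 1.2), 2)
  sp2 <- spearman_association(yy, gg)
  rho_manual <- {
    rx <- rank(yy); rg <- rank(gg)
    sum((rx - mean(rx)) * (rg - mean(rg))) /
      sqrt(sum((rx - mean(rx))^2) * sum((rg - mean(rg))^2))
  }
  expect_equal(sp2$rho, rho_manual)
  # constant input is flagged, not an error
  expect_true(spearman_association(rep(1, 12), rep(0:2, 4))$degenerate)
  expect_error(spearman_association(1:5, c(0, 1, 2, 0, 1)),
               "at least 10")
})

test_that("type-I error matches the nominal level under permutation", {
  set.seed(9)
  n <- 300
  g <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.44, 0.11))
  y <- rnorm(n)
  ps <- replicate(2000, spearman_association(sample(y), g)$p_nominal)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 2 * se)
})

test_that("Bonferroni correction is capped and monotone", {
  expect_equal(round(bonferroni(5.5e-8, 587111), 3), 0.032)
  expect_equal(round(bonferroni(6.5e-8, 587111), 3), 0.038)
  expect_equal(bonferroni(0.5, 10), 1)
  p <- seq(1e-8, 1e-2, length.out = 20)
  expect_true(all(diff(bonferroni(p, 1000)) >= 0))
  expect_true(all(bonferroni(1e-4, c(10, 100, 1000)) ==
                    c(1e-3, 1e-2, 1e-1)))
  expect_error(bonferroni(0.5, 0), ">= 1")
})

test_that("genotype summaries partition the samples", {
  set.seed(43)
  g <- sample(0:2, 60, replace = TRUE)
  y <- rnorm(60)
  gs <- genotype_summary(y, g)
  expect_equal(sum(gs$n), 60)
  expect_equal(gs$dosage, 0:2)
  # constant phenotype: equal means, zero sem
  gs2 <- genotype_summary(rep(2.5, 60), g)
  expect_true(all(gs2$mean == 2.5))
  expect_true(all(gs2$sem == 0))
  # missing dosages excluded
  g[1:5] <- NA
  expect_equal(sum(genotype_summary(y, g)$n), 55)
})

test_that("subsample consistency reports per-site effects and signs", {
  set.seed(47)
  n <- 300
  g <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.44, 0.11))
  y <- 0.5 * g + rnorm(n)
  site <- rep(c("Zurich", "Basel"), each = n / 2)
  res <- subsample_consistency(y, g, site)
  expect_equal(nrow(res$by_subsample), 2)
  expect_true(res$sign_agreement)
  expect_equal(res$by_subsample$rho[res$by_subsample$subsample == "Basel"],
               spearman_association(y[site == "Basel"],
                                    g[site == "Basel"])$rho)
  # flipping one site's phenotype flips its sign
  y2 <- y
  y2[site == "Basel"] <- -y2[site == "Basel"]
  res2 <- subsample_consistency(y2, g, site)
  expect_false(res2$sign_agreement)
  # identical subsamples give identical rho
  res3 <- subsample_consistency(c(y, y), c(g, g),
                                rep(c("a", "b"), each = n))
  expect_equal(res3$by_subsample$rho[1], res3$by_subsample$rho[2])
})

test_that("marker-wide scans sort by nominal p and correct family-wise", {
  set.seed(53)
  n <- 150
  d <- cbind(hit = sample(0:2, n, TRUE), null1 = sample(0:2, n, TRUE),
             null2 = sample(0:2, n, TRUE))
  rownames(d) <- paste0("s", 1:n)
  y <- 0.8 * d[, "hit"] + rnorm(n)
  scan <- association_scan(y, genotype_matrix(d))
  expect_equal(scan$marker_id[1], "hit")
  expect_true(!is.unsorted(scan$p_nominal))
  expect_equal(scan$p_bonferroni,
               pmin(1, scan$p_nominal * 3))
  res <- associate_marker(y, d[, "hit"], "hit", n_tests = 3)
  expect_equal(res$p_bonferroni, bonferroni(res$p_nominal, 3))
  expect_equal(sum(res$by_genotype$n), n)
})
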