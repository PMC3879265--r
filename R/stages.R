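# Population-level estimation: fixed-parameter search (stage 1),
# breadth-limited refinement (stage 2), combination averaging
# (stage 3), model selection across free/fixed partitions, and the
# bootstrap over per-subject hill-climbing end points.

# cheap per-subject fit used inside population scans: grid + coarse
# climbs only, no 1% refinement
fit_subject_quick <- function(observed, spec, dispersion, config, design,
                              subject_seed = 0) {
  ranges <- param_ranges()
  grid <- grid_candidates(spec, ranges, config$free_levels,
                          config$fixed_levels)
  theta <- full_theta_matrix(grid$free, spec)
  pms <- expected_pm_matrix(theta, design)
  chi2 <- colSums((t(pms) - observed)^2 / dispersion)
  ord <- order_by_chi2(chi2, grid$free)
  starts <- grid$free[ord[seq_len(min(config$n_starts, nrow(grid$free)))],
                      , drop = FALSE]
  obj <- function(free_values) {
    th <- full_theta(free_values, spec)
    chi_square(observed, expected_pm(th, design), dispersion)
  }
  res <- lapply(seq_len(nrow(starts)), function(i) {
    hill_climb(stats::setNames(as.numeric(starts[i, ]), spec$free), obj,
               step_fraction = config$step_coarse,
               ranges = ranges[spec$free, ],
               order_seed = 1000003 * subject_seed + i)
  })
  vals <- vapply(res, `[[`, numeric(1), "value")
  b <- which.min(vals)
  list(free = res[[b]]$par, chi2 = vals[b])
}

# mean chi2 over the cohort after quick-fitting every subject with the
# given fixed values
cohort_mean_chi2 <- function(pm_table, spec, fixed_values, dispersion,
                             config, design) {
  sp <- model_spec(free = spec$free, fixed_values = fixed_values)
  obs <- as.matrix(pm_table[, pm_names()])
  # position-independent seeding keeps cohort summaries invariant
  # under subject reordering
  vals <- vapply(seq_len(nrow(obs)), function(i) {
    fit_subject_quick(as.numeric(obs[i, ]), sp, dispersion, config, design,
                      subject_seed = 0)$chi2
  }, numeric(1))
  mean(vals)
}

#' Stage-1 estimation of the population-fixed parameters
#'
#' Scans a regular grid over the three fixed parameters (default
#' `4^3 = 64` candidate sets), quick-fits every subject under each
#' candidate, keeps the candidates with the best cohort-mean
#' chi-square, hill-climbs each kept candidate at 5% steps while the
#' per-subject free parameters are held at their fitted values, and
#' finally re-fits the cohort (with 1% refinement) under the winning
#' fixed values.
#'
#' @param pm_table data.frame with columns `pm1`..`pm8` (and
#'   optionally `subject_id`).
#' @param spec a [model_spec()]; its `fixed_values` are ignored and
#'   re-estimated.
#' @param config a [fit_config()].
#' @param design a [task_design()].
#' @return List of class `fixed_estimate`: `fixed_values`,
#'   `mean_chi2` (after the final cohort re-fit), `candidates`
#'   (ranked grid table), `climbed` (hill-climbing end points with
#'   their cohort-mean chi-square, best first) and `cohort_fit`.
#' @export
estimate_fixed <- function(pm_table, spec = model_spec(),
                           config = fit_config("desk"),
                           design = task_design()) {
  if (nrow(pm_table) == 0) stop("empty cohort")
  dispersion <- pm_dispersion(pm_table)
  ranges <- param_ranges()
  grid <- grid_candidates(spec, ranges, config$free_levels,
                          config$fixed_levels)
  obs <- as.matrix(pm_table[, pm_names()])

  scan_one <- function(fv) {
    sp <- model_spec(free = spec$free,
                     fixed_values = stats::setNames(as.numeric(fv),
                                                    spec$fixed))
    fits <- lapply(seq_len(nrow(obs)), function(i)
      fit_subject_quick(as.numeric(obs[i, ]), sp, dispersion, config,
                        design, subject_seed = 0))
    list(mean_chi2 = mean(vapply(fits, `[[`, numeric(1), "chi2")),
         free = do.call(rbind, lapply(fits, `[[`, "free")))
  }
  scans <- lapply(seq_len(nrow(grid$fixed)),
                  function(k) scan_one(grid$fixed[k, ]))
  mean_chi2 <- vapply(scans, `[[`, numeric(1), "mean_chi2")
  candidates <- data.frame(grid$fixed, mean_chi2 = mean_chi2)
  ordc <- order_by_chi2(mean_chi2, grid$fixed)
  candidates <- candidates[ordc, ]
  keep <- ordc[seq_len(min(config$n_keep_fixed, length(ordc)))]

  # climb fixed parameters holding the per-subject free estimates
  climbed <- lapply(seq_along(keep), function(j) {
    k <- keep[j]
    free_mat <- scans[[k]]$free
    objf <- function(fv) {
      th <- full_theta_matrix(free_mat,
                              model_spec(free = spec$free,
                                         fixed_values = stats::setNames(
                                           as.numeric(fv), spec$fixed)))
      pms <- expected_pm_matrix(th, design)
      mean(colSums((t(pms) - t(obs))^2 / dispersion))
    }
    hill_climb(stats::setNames(as.numeric(grid$fixed[k, ]), spec$fixed),
               objf, step_fraction = config$step_coarse,
               ranges = ranges[spec$fixed, ], order_seed = 77 + j)
  })
  cl_par <- do.call(rbind, lapply(climbed, `[[`, "par"))
  cl_val <- vapply(climbed, `[[`, numeric(1), "value")
  ordk <- order_by_chi2(cl_val, cl_par)
  climbed_tab <- data.frame(cl_par[ordk, , drop = FALSE],
                            mean_chi2 = cl_val[ordk])

  best_fixed <- stats::setNames(as.numeric(cl_par[ordk[1], ]), spec$fixed)
  final_spec <- model_spec(free = spec$free, fixed_values = best_fixed)
  cohort <- fit_cohort(pm_table, final_spec, config, design,
                       dispersion = dispersion)
  structure(list(fixed_values = best_fixed, mean_chi2 = cohort$mean_chi2,
                 candidates = candidates, climbed = climbed_tab,
                 cohort_fit = cohort, spec = final_spec),
            class = "fixed_estimate")
}

#' @exportS3Method
print.fixed_estimate <- function(x, ...) {
  cat("Fixed-parameter estimate:",
      paste(sprintf("%s = %.4g", names(x$fixed_values), x$fixed_values),
            collapse = ", "),
      sprintf("(cohort mean chi2 = %.4f)\n", x$mean_chi2))
  invisible(x)
}

#' Stage-2 refinement of the fixed parameters
#'
#' From each starting fixed-parameter set, single steps of 5% of the
#' range in both directions along each fixed parameter are evaluated
#' by re-fitting the whole cohort; every step that improves the
#' cohort-mean chi-square becomes a new starting point (breadth
#' limited to `config$max_live_starts` live starts). Returns all
#' evaluated sets ranked by cohort-mean chi-square.
#'
#' @inheritParams estimate_fixed
#' @param start_sets matrix/data.frame of fixed-parameter sets
#'   (columns = `spec$fixed`), e.g. the best rows of
#'   [estimate_fixed()]'s `climbed` table.
#' @return List of class `fixed_refinement` with `evaluated` (ranked
#'   data.frame of fixed sets and `mean_chi2`), `best_fixed` and
#'   `best_chi2`.
#' @export
refine_fixed <- function(pm_table, spec, start_sets,
                         config = fit_config("desk"),
                         design = task_design()) {
  dispersion <- pm_dispersion(pm_table)
  ranges <- param_ranges()[spec$fixed, ]
  step <- config$step_coarse * (ranges$upper - ranges$lower)
  seen <- new.env(parent = emptyenv())
  key <- function(fv) paste(signif(fv, 10), collapse = "/")
  evaluate <- function(fv) {
    k <- key(fv)
    if (!is.null(seen[[k]])) return(seen[[k]])
    v <- cohort_mean_chi2(pm_table, spec,
                          stats::setNames(as.numeric(fv), spec$fixed),
                          dispersion, config, design)
    seen[[k]] <- v
    v
  }
  start_sets <- as.matrix(start_sets)[, spec$fixed, drop = FALSE]
  queue <- lapply(seq_len(nrow(start_sets)), function(i) {
    fv <- as.numeric(start_sets[i, ])
    list(fv = fv, value = evaluate(fv))
  })
  results <- queue
  n_started <- length(queue)
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    for (j in seq_along(node$fv)) {
      for (dir in c(1, -1)) {
        cand <- node$fv
        cand[j] <- min(ranges$upper[j],
                       max(ranges$lower[j], cand[j] + dir * step[j]))
        if (cand[j] == node$fv[j] || !is.null(seen[[key(cand)]])) next
        v <- evaluate(cand)
        rec <- list(fv = cand, value = v)
        results[[length(results) + 1]] <- rec
        if (v < node$value && n_started < config$max_live_starts) {
          queue[[length(queue) + 1]] <- rec
          n_started <- n_started + 1
        }
      }
    }
  }
  tab <- data.frame(do.call(rbind, lapply(results, `[[`, "fv")),
                    mean_chi2 = vapply(results, `[[`, numeric(1), "value"))
  names(tab)[seq_along(spec$fixed)] <- spec$fixed
  tab <- tab[order_by_chi2(tab$mean_chi2,
                           as.matrix(tab[, spec$fixed])), ]
  structure(list(evaluated = tab,
                 best_fixed = stats::setNames(
                   as.numeric(tab[1, spec$fixed]), spec$fixed),
                 best_chi2 = tab$mean_chi2[1]),
            class = "fixed_refinement")
}

#' Stage-3 combination averaging of fixed-parameter sets
#'
#' Evaluates the component-wise average of every non-empty subset of
#' up to ten fixed-parameter sets (`2^k - 1` subsets) and returns the
#' best. Averaging overcomes the step-size granularity of hill
#' climbing.
#'
#' @param fixed_sets matrix/data.frame of at most 10 fixed-parameter
#'   sets (one per row).
#' @param evaluate function mapping a fixed-parameter vector to the
#'   cohort-mean chi-square (e.g. a closure over
#'   [fit_cohort()]).
#' @return List with `best_fixed`, `best_chi2`, `n_subsets` and the
#'   full `table` of subset averages and values.
#' @export
combination_average <- function(fixed_sets, evaluate) {
  fixed_sets <- as.matrix(fixed_sets)
  k <- nrow(fixed_sets)
  if (k < 1 || k > 10) stop("between 1 and 10 fixed sets required")
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  avgs <- t(vapply(subsets, function(ix)
    colMeans(fixed_sets[ix, , drop = FALSE]), numeric(ncol(fixed_sets))))
  vals <- vapply(seq_len(nrow(avgs)),
                 function(i) evaluate(avgs[i, ]), numeric(1))
  ord <- order_by_chi2(vals, avgs)
  tab <- data.frame(avgs[ord, , drop = FALSE], mean_chi2 = vals[ord],
                    subset = vapply(subsets[ord], paste, character(1),
                                    collapse = "+"))
  list(best_fixed = stats::setNames(as.numeric(avgs[ord[1], ]),
                                    colnames(fixed_sets)),
       best_chi2 = vals[ord[1]],
       n_subsets = length(subsets),
       table = tab)
}

#' Model selection over free/fixed partitions
#'
#' Enumerates all `choose(8, 3) = 56` ways of fixing three of the
#' eight parameters and ranks them by the cohort-mean chi-square of a
#' (coarse) fixed-parameter estimation. The two best models are
#' flagged for refinement.
#'
#' @inheritParams estimate_fixed
#' @param evaluate optional function `f(spec)` returning the
#'   cohort-mean chi-square for one [model_spec()]; defaults to
#'   running [estimate_fixed()] at the given `config`. Injectable so
#'   the ranking contract can be exercised without full estimation.
#' @param n_models number of top-ranked partitions to evaluate fully
#'   (all 56 when `NULL`; presets reduce this).
#' @return Data.frame of class `model_selection`, one row per
#'   partition, columns `free`, `fixed`, `mean_chi2`, `refine`
#'   (TRUE for the top two), ranked best first.
#' @export
select_model <- function(pm_table, config = fit_config("desk"),
                         design = task_design(), evaluate = NULL,
                         n_models = NULL) {
  specs <- enumerate_model_specs()
  if (is.null(evaluate))
    evaluate <- function(sp)
      estimate_fixed(pm_table, sp, config, design)$mean_chi2
  if (is.null(n_models)) n_models <- length(specs)
  vals <- vapply(specs[seq_len(min(n_models, length(specs)))], evaluate,
                 numeric(1))
  tab <- data.frame(
    free = vapply(specs, function(s) paste(s$free, collapse = ","),
                  character(1)),
    fixed = vapply(specs, function(s) paste(s$fixed, collapse = ","),
                   character(1)),
    mean_chi2 = c(vals, rep(NA_real_, length(specs) - length(vals))),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$mean_chi2), ]
  tab$refine <- FALSE
  tab$refine[seq_len(min(2, sum(!is.na(tab$mean_chi2))))] <- TRUE
  class(tab) <- c("model_selection", "data.frame")
  tab
}

#' Bootstrap over per-subject hill-climbing end points
#'
#' Generates resampled cohorts in which each subject's parameters are
#' one of their stored best-fitting end-point sets, drawn uniformly.
#' Downstream statistics (e.g. a Spearman association p-value) are
#' computed per sample and summarised by their median.
#'
#' @param top_sets list with one data.frame per subject (rows = the
#'   stored parameter sets, columns [param_names()]), e.g.
#'   `lapply(cohort$fits, function(f) f$top_sets)`.
#' @param n_samples number of bootstrap samples (default 10000).
#' @param seed integer seed.
#' @return Object of class `recall_bootstrap` with `$n_samples`,
#'   `$index` (sample x subject chosen-set indices) and `$draw(i)`
#'   returning the i-th resampled parameter matrix (subjects x 8).
#' @export
bootstrap_parameter_sets <- function(top_sets, n_samples = 10000, seed = 1) {
  if (!length(top_sets) || any(!vapply(top_sets, nrow, integer(1))))
    stop("every subject needs at least one stored parameter set")
  n_subj <- length(top_sets)
  sizes <- vapply(top_sets, nrow, integer(1))
  index <- with_seed(seed, {
    vapply(sizes, function(k) sample.int(k, n_samples, replace = TRUE),
           integer(n_samples))
  })
  index <- matrix(index, nrow = n_samples)
  mats <- lapply(top_sets, function(ts) as.matrix(ts[, param_names()]))
  draw <- function(i) {
    out <- t(vapply(seq_len(n_subj),
                    function(j) mats[[j]][index[i, j], ], numeric(8)))
    colnames(out) <- param_names()
    out
  }
  structure(list(n_samples = n_samples, n_subjects = n_subj,
                 index = index, draw = draw),
            class = "recall_bootstrap")
}

#' Per-sample statistics and their median over a bootstrap
#'
#' @param bs a [bootstrap_parameter_sets()] object.
#' @param statistic function of one resampled parameter matrix.
#' @return List with `values` (one per sample) and `median`.
#' @export
bootstrap_summary <- function(bs, statistic) {
  values <- vapply(seq_len(bs$n_samples),
                   function(i) statistic(bs$draw(i)), numeric(1))
  list(values = values, median = stats::median(values))
}

#' Full three-stage population estimation
#'
#' Convenience wrapper running stage 1 ([estimate_fixed()]), stage 2
#' ([refine_fixed()] from the two best stage-1 end points) and stage
#' 3 ([combination_average()] over the ten best stage-2 sets),
#' followed by a final cohort fit at the stage-3 fixed values. The
#' cohort-mean chi-square is non-increasing across the reported
#' stages.
#'
#' @inheritParams estimate_fixed
#' @return List of class `recall_pipeline` with per-stage fixed
#'   values and mean chi-squares and the final `cohort_fit`.
#' @export
run_estimation <- function(pm_table, spec = model_spec(),
                           config = fit_config("desk"),
                           design = task_design()) {
  dispersion <- pm_dispersion(pm_table)
  s1 <- estimate_fixed(pm_table, spec, config, design)
  seen <- new.env(parent = emptyenv())
  evaluate <- function(fv) {
    k <- paste(signif(fv, 10), collapse = "/")
    if (is.null(seen[[k]]))
      seen[[k]] <- cohort_mean_chi2(
        pm_table, spec, stats::setNames(as.numeric(fv), spec$fixed),
        dispersion, config, design)
    seen[[k]]
  }
  starts <- s1$climbed[seq_len(min(2, nrow(s1$climbed))), spec$fixed,
                       drop = FALSE]
  s2 <- refine_fixed(pm_table, spec, starts, config, design)
  top10 <- s2$evaluated[seq_len(min(10, nrow(s2$evaluated))), spec$fixed,
                        drop = FALSE]
  s3 <- combination_average(top10, evaluate)
  # stage-2/3 values share the quick-fit evaluator; keep the better
  best_fixed <- if (s3$best_chi2 <= s2$best_chi2) s3$best_fixed
                else s2$best_fixed
  final_spec <- model_spec(free = spec$free, fixed_values = best_fixed)
  cohort <- fit_cohort(pm_table, final_spec, config, design,
                       dispersion = dispersion)
  structure(list(
    stage1 = list(fixed = s1$fixed_values,
                  mean_chi2 = evaluate(as.numeric(s1$fixed_values))),
    stage2 = list(fixed = s2$best_fixed, mean_chi2 = s2$best_chi2),
    stage3 = list(fixed = s3$best_fixed, mean_chi2 = min(s3$best_chi2,
                                                         s2$best_chi2)),
    final_spec = final_spec,
    cohort_fit = cohort
  ), class = "recall_pipeline")
}

#' @exportS3Method
print.recall_pipeline <- function(x, ...) {
  cat("Three-stage population estimation\n")
  for (st in c("stage1", "stage2", "stage3"))
    cat(sprintf("  %s: mean chi2 = %.4f (%s)\n", st, x[[st]]$mean_chi2,
                paste(sprintf("%s=%.3g", names(x[[st]]$fixed),
                              x[[st]]$fixed), collapse = ", ")))
  print(x$cohort_fit)
  invisible(x)
}
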