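#' Chi-square goodness of fit between observed and modeled measures
#'
#' `sum_i (PM_i_obs - PM_i_mod)^2 / var_i` over the eight performance
#' measures, where `var_i` is the across-cohort variance of PM_i.
#'
#' @param observed,modeled numeric vectors of 8 performance measures.
#' @param dispersion per-measure cohort variances, see
#'   [pm_dispersion()].
#' @return Non-negative scalar.
#' @export
chi_square <- function(observed, modeled, dispersion) {
  if (length(observed) != 8 || length(modeled) != 8 ||
      length(dispersion) != 8)
    stop("observed, modeled and dispersion must have length 8")
  if (any(dispersion <= 0))
    stop("zero or negative PM variance; apply a variance floor (see pm_dispersion)")
  sum((observed - modeled)^2 / dispersion)
}

#' Across-cohort variance of each performance measure
#'
#' The denominator of the chi-square statistic. A floor (default 0.25)
#' protects against degenerate cohorts where a measure is nearly
#' constant.
#'
#' @param pm_table matrix/data.frame of subjects x 8 measures.
#' @param floor minimum admissible variance.
#' @return Named vector of 8 variances.
#' @export
pm_dispersion <- function(pm_table, floor = 0.25) {
  pm <- as.matrix(pm_table[, pm_names(), drop = FALSE])
  v <- apply(pm, 2, stats::var)
  pmax(v, floor)
}

#' Upper-tail chi-square fit probability
#'
#' `P(chi2, nu)`: the probability that a chi-square variable with `nu`
#' degrees of freedom exceeds the observed statistic. Values above
#' 0.05 indicate no detectable difference between modeled and
#' observed performance measures. With 8 measures and 5 free
#' parameters, `nu = 3`.
#'
#' @param chi2 observed statistic (>= 0).
#' @param nu degrees of freedom.
#' @return Probability in \[0, 1\].
#' @examples
#' fit_quality(1.5057, 3)
#' @export
fit_quality <- function(chi2, nu = 3) {
  if (any(chi2 < 0)) stop("'chi2' must be non-negative")
  if (any(nu < 1)) stop("'nu' must be >= 1")
  stats::pchisq(chi2, df = nu, lower.tail = FALSE)
}

#' Regular-interval starting grids for free and fixed parameters
#'
#' Free parameters take `free_levels` values at odd fractions
#' `1/(2L), 3/(2L), ...` of their range (8 levels: 1/16, 3/16, ...,
#' 15/16); fixed parameters take `fixed_levels` values the same way
#' (4 levels: 1/8, 3/8, 5/8, 7/8). The Cartesian products give
#' `free_levels^5` candidate free sets and `fixed_levels^3` candidate
#' fixed sets (defaults: 8^5 = 32768 and 4^3 = 64).
#'
#' @param spec a [model_spec()].
#' @param ranges parameter ranges, see [param_ranges()].
#' @param free_levels,fixed_levels grid levels per free / fixed
#'   parameter.
#' @return List with matrices `free` (columns `spec$free`) and
#'   `fixed` (columns `spec$fixed`).
#' @export
grid_candidates <- function(spec, ranges = param_ranges(), free_levels = 8,
                            fixed_levels = 4) {
  level_values <- function(name, L) {
    lo <- ranges[name, "lower"]; hi <- ranges[name, "upper"]
    lo + (2 * seq_len(L) - 1) / (2 * L) * (hi - lo)
  }
  free <- as.matrix(expand.grid(lapply(spec$free, level_values,
                                       L = free_levels),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(free) <- spec$free
  fixed <- as.matrix(expand.grid(lapply(spec$fixed, level_values,
                                        L = fixed_levels),
                                 KEEP.OUT.ATTRS = FALSE))
  colnames(fixed) <- spec$fixed
  list(free = free, fixed = fixed)
}

# Lehmer generator for the deterministic step ordering of the hill
# climb: does not touch R's global RNG stream.
lehmer <- function(seed) {
  state <- (as.numeric(seed) %% 2147483646) + 1
  function() {
    state <<- (48271 * state) %% 2147483647
    state / 2147483647
  }
}

lehmer_perm <- function(rng, n) {
  order(vapply(seq_len(n), function(i) rng(), numeric(1)))
}

#' Deterministic first-improvement hill climbing
#'
#' From a starting point, candidate moves of one step (a fixed
#' fraction of each parameter's range) in either direction along each
#' coordinate are examined in a pseudorandom but seed-reproducible
#' order; the first move that lowers the objective is taken, and the
#' procedure repeats until no single step improves. Steps are clipped
#' to the parameter ranges.
#'
#' @param start named numeric starting values (within ranges).
#' @param objective function of a named vector returning the value to
#'   minimise.
#' @param step_fraction step size as a fraction of each range
#'   (5% in the coarse stage, 1% in refinement).
#' @param ranges rows of [param_ranges()] for the climbed parameters.
#' @param order_seed integer seed for the step ordering.
#' @return List with `par` (endpoint), `value` (objective there) and
#'   `n_eval`.
#' @export
hill_climb <- function(start, objective, step_fraction = 0.05,
                       ranges = param_ranges()[names(start), ],
                       order_seed = 1) {
  par <- start
  k <- length(par)
  lo <- ranges$lower; hi <- ranges$upper
  if (any(par < lo | par > hi)) stop("start outside ranges")
  step <- step_fraction * (hi - lo)
  value <- objective(par)
  n_eval <- 1L
  rng <- lehmer(order_seed)
  moves <- cbind(rep(seq_len(k), 2), rep(c(1, -1), each = k))
  repeat {
    improved <- FALSE
    for (idx in lehmer_perm(rng, nrow(moves))) {
      j <- moves[idx, 1]; dir <- moves[idx, 2]
      cand <- par
      cand[j] <- min(hi[j], max(lo[j], par[j] + dir * step[j]))
      if (cand[j] == par[j]) next
      v <- objective(cand)
      n_eval <- n_eval + 1L
      if (v < value) {
        par <- cand
        value <- v
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(par = par, value = value, n_eval = n_eval)
}

#' Fitting configuration presets
#'
#' Bundles the enumeration sizes and step fractions of the estimation
#' procedure. Preset `"paper"` is the full-scale procedure (8^5 free
#' grid, 4^3 fixed grid, 20 fixed sets kept, all 56 models); preset
#' `"desk"` is a reduced configuration (4^5 free grid, 3^3 fixed
#' grid, 5 fixed sets kept, top 8 models) sized so the whole pipeline
#' runs interactively.
#'
#' @param preset `"paper"` or `"desk"`.
#' @param ... named overrides of individual fields.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    paper = list(free_levels = 8, fixed_levels = 4, n_starts = 10,
                 n_keep_fixed = 20, n_models = 56, step_coarse = 0.05,
                 step_fine = 0.01, max_live_starts = 32, seed = 1),
    desk = list(free_levels = 4, fixed_levels = 3, n_starts = 10,
                n_keep_fixed = 5, n_models = 8, step_coarse = 0.05,
                step_fine = 0.01, max_live_starts = 32, seed = 1)
  )
  cfg$preset <- preset
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown fit_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "fit_config")
}

# order by chi2 with lexicographic tie-break over parameter columns
order_by_chi2 <- function(chi2, par_matrix) {
  do.call(order, c(list(chi2), lapply(seq_len(ncol(par_matrix)),
                                      function(j) par_matrix[, j])))
}

#' Fit the recall model to one subject
#'
#' The per-subject estimation stage: a regular grid over the five
#' free parameters is scanned (fixed parameters held at the values in
#' `spec`), the ten best grid points seed deterministic hill climbs
#' at 5% steps, their endpoints are refined at 1% steps, and the
#' component-wise average of the refined endpoints is also evaluated;
#' the best point wins.
#'
#' @param observed named numeric vector of 8 observed performance
#'   measures.
#' @param spec a [model_spec()] with fixed values set.
#' @param dispersion cohort PM variances, see [pm_dispersion()].
#' @param config a [fit_config()].
#' @param design a [task_design()].
#' @param subject_seed integer folded into the hill-climb step
#'   ordering so different subjects use different (but reproducible)
#'   orderings.
#' @return Object of class `recall_fit`: best parameters, chi-square,
#'   fit probability `P(chi2, nu)` with `nu = 8 - 5 = 3`, modeled
#'   measures, and the 10 refined endpoint sets.
#' @examples
#' \donttest{
#' pm <- expected_pm(recall_params())
#' fit <- fit_recall(pm, dispersion = rep(1, 8))
#' coef(fit)
#' }
#' @export
fit_recall <- function(observed, spec = model_spec(), dispersion,
                       config = fit_config("desk"), design = task_design(),
                       subject_seed = 0) {
  observed <- as.numeric(observed[pm_names()])
  if (any(is.na(observed))) stop("observed measures must be pm1..pm8")
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
  climb <- function(st, i, step) {
    hill_climb(stats::setNames(as.numeric(st), spec$free), obj,
               step_fraction = step, ranges = ranges[spec$free, ],
               order_seed = 1000003 * subject_seed + i)
  }
  coarse <- lapply(seq_len(nrow(starts)),
                   function(i) climb(starts[i, ], i, config$step_coarse))
  fine <- lapply(seq_along(coarse),
                 function(i) climb(coarse[[i]]$par, 100 + i,
                                   config$step_fine))
  end_par <- do.call(rbind, lapply(fine, `[[`, "par"))
  end_val <- vapply(fine, `[[`, numeric(1), "value")
  avg <- colMeans(end_par)
  avg_val <- obj(avg)
  if (avg_val < min(end_val)) {
    best_free <- avg
    best_val <- avg_val
  } else {
    b <- which.min(end_val)
    best_free <- end_par[b, ]
    best_val <- end_val[b]
  }
  ord2 <- order_by_chi2(end_val, end_par)
  top_sets <- data.frame(full_theta_matrix(end_par[ord2, , drop = FALSE],
                                           spec),
                         chi2 = end_val[ord2])
  best_params <- as_params(full_theta(best_free, spec))
  nu <- 8 - length(spec$free)
  modeled <- expected_pm(best_params, design)
  structure(list(
    best_params = best_params,
    chi2 = best_val,
    nu = nu,
    p_fit = fit_quality(best_val, nu),
    modeled_pms = modeled,
    observed_pms = stats::setNames(observed, pm_names()),
    top_sets = top_sets,
    spec = spec,
    dispersion = dispersion,
    design = design
  ), class = "recall_fit")
}

#' Fit the recall model to every subject of a cohort
#'
#' Applies [fit_recall()] subject by subject with the cohort PM
#' variances as chi-square denominators.
#'
#' @param pm_table data.frame with `subject_id` and `pm1`..`pm8`.
#' @param spec,config,design as in [fit_recall()].
#' @param dispersion optional; computed from the cohort by default.
#' @return Object of class `recall_cohort_fit`: a `parameters`
#'   data.frame (subject_id, 8 parameters, chi2, p_fit), the list of
#'   per-subject fits, and the cohort mean chi-square.
#' @export
fit_cohort <- function(pm_table, spec = model_spec(),
                       config = fit_config("desk"), design = task_design(),
                       dispersion = pm_dispersion(pm_table)) {
  ids <- if ("subject_id" %in% names(pm_table)) pm_table$subject_id
         else seq_len(nrow(pm_table))
  fits <- lapply(seq_len(nrow(pm_table)), function(i) {
    fit_recall(unlist(pm_table[i, pm_names()]), spec, dispersion, config,
               design, subject_seed = i)
  })
  par_tab <- data.frame(
    subject_id = ids,
    do.call(rbind, lapply(fits, function(f) unclass(f$best_params))),
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    p_fit = vapply(fits, `[[`, numeric(1), "p_fit"),
    stringsAsFactors = FALSE
  )
  structure(list(parameters = par_tab, fits = fits, spec = spec,
                 mean_chi2 = mean(par_tab$chi2), dispersion = dispersion,
                 config = config, design = design),
            class = "recall_cohort_fit")
}
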