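#' @exportS3Method
print.recall_fit <- function(x, ...) {
  cat("Recall-model fit (chi-square)\n")
  cat(sprintf("  chi2 = %.4f on nu = %d, P(chi2, nu) = %.3f (%s)\n",
              x$chi2, x$nu, x$p_fit,
              if (x$p_fit > 0.05) "adequate" else "poor"))
  cat("  free:", paste(x$spec$free, collapse = ", "), "\n")
  print(round(unclass(x$best_params), 4))
  invisible(x)
}

#' @export
summary.recall_fit <- function(object, ...) {
  tab <- rbind(observed = object$observed_pms,
               modeled = object$modeled_pms,
               residual = object$observed_pms - object$modeled_pms)
  structure(list(fit = object, pm_table = tab), class = "summary.recall_fit")
}

#' @exportS3Method
print.summary.recall_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPerformance measures:\n")
  print(round(x$pm_table, 3))
  sd_spread <- apply(x$fit$top_sets[, param_names()], 2, stats::sd)
  cat("\nSpread of the 10 hill-climbing end points (sd):\n")
  print(round(sd_spread, 4))
  invisible(x)
}

#' @export
coef.recall_fit <- function(object, ...) unclass(object$best_params)

#' @export
fitted.recall_fit <- function(object, ...) object$modeled_pms

#' @export
residuals.recall_fit <- function(object, ...) {
  object$observed_pms - object$modeled_pms
}

#' Simulate recall sessions from a fitted model
#'
#' @param object a `recall_fit`.
#' @param nsim number of sessions.
#' @param seed integer seed (mandatory for reproducibility).
#' @param ... unused.
#' @return Data.frame of simulated `pm1`..`pm8`, one row per session.
#' @export
simulate.recall_fit <- function(object, nsim = 1, seed = 1, ...) {
  as.data.frame(do.call(rbind, lapply(seq_len(nsim), function(i) {
    simulate_subject(object$best_params, object$design,
                     seed = seed + i - 1)$pm
  })))
}

#' Observed versus modeled performance measures
#'
#' @param x a `recall_fit`.
#' @param ... passed to [graphics::barplot()].
#' @exportS3Method
plot.recall_fit <- function(x, ...) {
  h <- rbind(observed = x$observed_pms, modeled = x$modeled_pms)
  graphics::barplot(h, beside = TRUE, names.arg = pm_names(),
                    legend.text = rownames(h),
                    ylab = "words", main = sprintf(
                      "chi2 = %.2f, P = %.2f", x$chi2, x$p_fit), ...)
  invisible(x)
}

#' @exportS3Method
print.recall_cohort_fit <- function(x, ...) {
  n <- nrow(x$parameters)
  cat(sprintf("Cohort fit: %d subjects, mean chi2 = %.4f\n", n, x$mean_chi2))
  cat(sprintf("  %.1f%% pass P(chi2, %d) > 0.05\n",
              100 * mean(x$parameters$p_fit > 0.05), 8 - length(x$spec$free)))
  cat("  free:", paste(x$spec$free, collapse = ", "),
      "| fixed:", paste(sprintf("%s = %g", names(x$spec$fixed_values),
                                x$spec$fixed_values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.recall_cohort_fit <- function(object, ...) {
  p <- object$parameters
  stats <- t(apply(p[, param_names()], 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      q05 = unname(stats::quantile(v, 0.05)),
      q95 = unname(stats::quantile(v, 0.95)))))
  structure(list(cohort = object, param_stats = stats),
            class = "summary.recall_cohort_fit")
}

#' @exportS3Method
print.summary.recall_cohort_fit <- function(x, ...) {
  print(x$cohort)
  cat("\nFitted parameter distributions:\n")
  print(round(x$param_stats, 3))
  invisible(x)
}

#' @export
coef.recall_cohort_fit <- function(object, ...) {
  as.matrix(object$parameters[, param_names()])
}
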