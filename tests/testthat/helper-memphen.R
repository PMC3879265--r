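# shared fixtures: all generated in code, nothing on disk

# random parameter set drawn inside the search ranges (margin keeps
# quadrature away from the degenerate edges)
random_params <- function(margin = 0.02) {
  r <- param_ranges()
  v <- stats::runif(8, r$lower + margin * (r$upper - r$lower),
                    r$upper - margin * (r$upper - r$lower))
  names(v) <- param_names()
  structure(v, class = "recall_params")
}

# noise-free cohort: observed PMs are the exact model expectations at
# per-subject free parameters and common fixed values
exact_pm_cohort <- function(n, free_matrix, fixed_values,
                            spec = model_spec()) {
  obs <- t(apply(free_matrix, 1, function(fv) {
    th <- c(fv, fixed_values)[param_names()]
    names(th) <- param_names()
    expected_pm(structure(th, class = "recall_params"))
  }))
  tab <- data.frame(subject_id = paste0("s", seq_len(n)), obs,
                    stringsAsFactors = FALSE)
  names(tab)[-1] <- paste0("pm", 1:8)
  tab
}

range_fraction <- function(param, frac) {
  r <- param_ranges()
  r[param, "lower"] + frac * (r[param, "upper"] - r[param, "lower"])
}
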