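#' Names of the eight cognitive parameters
#'
#' Order used throughout the package: learning rate `alpha`, decision
#' threshold `beta`, forgetting rate `gamma`, emotional modulation
#' `eps_pos` / `eps_neg`, encoding-noise standard deviation `sigma`,
#' repetition-based memory improvement `c`, sigmoid steepness `s`.
#'
#' @return Character vector of length 8.
#' @export
param_names <- function() {
  c("alpha", "beta", "gamma", "eps_pos", "eps_neg", "sigma", "c", "s")
}

#' Parameter search ranges
#'
#' The estimation ranges for the eight model parameters: `alpha`,
#' `beta`, `eps_pos`, `eps_neg` and `sigma` in \[0.3, 3.5\], `c` in
#' \[1, 4.2\] (repetition must not weaken memories), `gamma` in
#' (0, 0.8\] and `s` in (0, 16\].
#'
#' @return A data.frame with columns `lower` and `upper`, one row per
#'   parameter, row names [param_names()].
#' @export
param_ranges <- function() {
  data.frame(
    lower = c(0.3, 0.3, 0, 0.3, 0.3, 0.3, 1, 0),
    upper = c(3.5, 3.5, 0.8, 3.5, 3.5, 3.5, 4.2, 16),
    row.names = param_names()
  )
}

#' Construct a full cognitive parameter set
#'
#' Bundles the eight parameters of the recall model into a validated
#' named numeric vector of class `recall_params`.
#'
#' @param alpha learning rate (mean initial memory strength of a
#'   neutral word).
#' @param beta decision threshold: only words with strength above
#'   `beta` are attempted in free recall.
#' @param gamma forgetting rate, multiplier applied to all strengths
#'   over the 5-minute delay (< 1).
#' @param eps_pos,eps_neg emotional modulation multipliers applied to
#'   the strengths of positive / negative words at encoding.
#' @param sigma standard deviation of the Gaussian encoding noise.
#' @param c repetition-based improvement multiplier for words written
#'   down at immediate recall (>= 1).
#' @param s steepness of the sigmoidal recall-success curve.
#' @param enforce_ranges if `TRUE` (default), values outside
#'   [param_ranges()] are an error. Switch off for analytic limit
#'   checks (e.g. `gamma` close to 1).
#' @return Named numeric vector of class `recall_params`.
#' @examples
#' recall_params(alpha = 1.93, beta = 1.27, eps_neg = 1.12)
#' @export
recall_params <- function(alpha = 1.93, beta = 1.27, gamma = 0.5,
                          eps_pos = 1.09, eps_neg = 1.12, sigma = 0.7,
                          c = 1.95, s = 4.133, enforce_ranges = TRUE) {
  th <- vapply(list(alpha, beta, gamma, eps_pos, eps_neg, sigma, c, s),
               function(x) as.numeric(x)[1], numeric(1))
  names(th) <- param_names()
  validate_params(th, enforce_ranges = enforce_ranges)
  structure(th, class = "recall_params")
}

validate_params <- function(theta, enforce_ranges = TRUE) {
  if (!is.numeric(theta) || length(theta) != 8)
    stop("parameter set must be numeric of length 8")
  if (is.null(names(theta)) || !identical(names(theta), param_names()))
    stop("parameter set must be named ", paste(param_names(), collapse = ", "))
  if (any(!is.finite(theta)))
    stop("non-finite parameter value")
  if (any(theta <= 0))
    stop("all parameters must be strictly positive")
  if (enforce_ranges) {
    r <- param_ranges()
    bad <- theta < r$lower | theta > r$upper
    if (any(bad))
      stop("parameter(s) outside estimation range: ",
           paste(param_names()[bad], collapse = ", "))
  }
  invisible(theta)
}

as_params <- function(x, enforce_ranges = TRUE) {
  x <- unlist(x)[param_names()]
  names(x) <- param_names()
  validate_params(x, enforce_ranges = enforce_ranges)
  structure(x, class = "recall_params")
}

#' @exportS3Method
print.recall_params <- function(x, ...) {
  cat("Recall-model parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Free/fixed partition of the model parameters
#'
#' A model specification names the 5 parameters estimated per subject
#' (free) and the 3 estimated once for the whole population (fixed),
#' with the fixed values. The default is the best-fitting partition:
#' `alpha`, `beta`, `c`, `eps_pos`, `eps_neg` free and `sigma`,
#' `gamma`, `s` fixed.
#'
#' @param free character vector of 5 free parameter names.
#' @param fixed_values named numeric vector giving values for the 3
#'   remaining parameters.
#' @return Object of class `model_spec` with elements `free`, `fixed`
#'   and `fixed_values`.
#' @examples
#' model_spec()
#' model_spec(free = c("alpha", "beta", "gamma", "eps_pos", "eps_neg"),
#'            fixed_values = c(sigma = 0.7, c = 1.2, s = 4.1))
#' @export
model_spec <- function(free = c("alpha", "beta", "c", "eps_pos", "eps_neg"),
                       fixed_values = c(sigma = 0.7, gamma = 0.5, s = 4.133)) {
  all_names <- param_names()
  if (length(free) != 5 || !all(free %in% all_names) || anyDuplicated(free))
    stop("'free' must name 5 distinct parameters")
  fixed <- setdiff(all_names, free)
  if (!setequal(names(fixed_values), fixed))
    stop("'fixed_values' must be named exactly ", paste(fixed, collapse = ", "))
  fixed_values <- fixed_values[fixed]
  r <- param_ranges()[fixed, ]
  if (any(fixed_values < r$lower | fixed_values > r$upper))
    stop("fixed value outside its range")
  structure(list(free = free, fixed = fixed,
                 fixed_values = fixed_values),
            class = "model_spec")
}

#' @exportS3Method
print.model_spec <- function(x, ...) {
  cat("Model specification\n")
  cat("  free (per subject):", paste(x$free, collapse = ", "), "\n")
  cat("  fixed (population):",
      paste(sprintf("%s = %g", names(x$fixed_values), x$fixed_values),
            collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all 5-free / 3-fixed model specifications
#'
#' All `choose(8, 3) = 56` ways of holding three of the eight
#' parameters fixed across the population.
#'
#' @param fixed_values optional named vector of fallback fixed values;
#'   defaults to range midpoints.
#' @return List of 56 [model_spec()] objects.
#' @export
enumerate_model_specs <- function(fixed_values = NULL) {
  r <- param_ranges()
  mid <- (r$lower + r$upper) / 2
  names(mid) <- param_names()
  if (!is.null(fixed_values)) mid[names(fixed_values)] <- fixed_values
  combos <- utils::combn(param_names(), 3, simplify = FALSE)
  lapply(combos, function(fx) {
    model_spec(free = setdiff(param_names(), fx), fixed_values = mid[fx])
  })
}

# assemble full 8-vector(s) from free values + spec
full_theta <- function(free_values, spec) {
  th <- numeric(8)
  names(th) <- param_names()
  th[spec$free] <- free_values
  th[spec$fixed] <- spec$fixed_values
  th
}

full_theta_matrix <- function(free_matrix, spec) {
  n <- nrow(free_matrix)
  th <- matrix(NA_real_, n, 8, dimnames = list(NULL, param_names()))
  th[, spec$free] <- free_matrix
  th[, spec$fixed] <- matrix(spec$fixed_values, n, 3, byrow = TRUE)
  th
}
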