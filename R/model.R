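#' Probability of correct recall given memory strength
#'
#' Logistic recall-success curve: a word attempted at strength `m`
#' is recalled correctly with probability `1 / (1 + exp(-s (m - m50)))`.
#'
#' @param m memory strength (vectorised).
#' @param s sigmoid steepness (> 0).
#' @param m50 strength at which success probability is 1/2 (> 0).
#' @return Probabilities in (0, 1).
#' @examples
#' recall_probability(1, s = 4.133)      # 0.5 at the centre
#' recall_probability(1 + log(3) / 2, 2) # 0.75
#' @export
recall_probability <- function(m, s, m50 = 1) {
  if (any(s <= 0)) stop("'s' must be positive")
  if (any(m50 <= 0)) stop("'m50' must be positive")
  1 / (1 + exp(-s * (m - m50)))
}

#' Distribution of initial memory strength at encoding
#'
#' At encoding a word of valence `v` receives strength
#' `m0 = eps_v * (alpha + N(0, sigma))`, i.e. Normal with mean
#' `eps_v * alpha` and sd `eps_v * sigma`, where `eps_v` is `eps_pos`
#' for positive, `eps_neg` for negative and 1 for neutral words.
#' The `"additive"` variant instead leaves the noise unscaled:
#' `m0 = eps_v * alpha + N(0, sigma)`.
#'
#' @param params a [recall_params()] vector.
#' @param valence one of `"neutral"`, `"positive"`, `"negative"`.
#' @param variant `"multiplicative"` (default) or `"additive"` noise
#'   treatment of the emotional modulation.
#' @return List with `mean` and `sd` of the Gaussian law of `m0`.
#' @examples
#' encoding_distribution(recall_params(alpha = 2, sigma = 0.5,
#'                                     eps_neg = 1.5), "negative")
#' @export
encoding_distribution <- function(params, valence = c("neutral", "positive",
                                                      "negative"),
                                  variant = c("multiplicative", "additive")) {
  valence <- match.arg(valence)
  variant <- match.arg(variant)
  eps <- switch(valence, neutral = 1, positive = unname(params["eps_pos"]),
                negative = unname(params["eps_neg"]))
  list(mean = eps * unname(params["alpha"]),
       sd = if (variant == "additive") unname(params["sigma"])
            else eps * unname(params["sigma"]))
}

#' Exact expected performance measures
#'
#' Computes the expectation of the eight performance measures under
#' the generative recall model by numerical integration over the
#' Gaussian law of initial memory strength, per valence: probability
#' of a correct immediate recall `E[1(m0 > beta) g(m0)]`, of an
#' immediate confabulative error `P(m0 > beta) - E[1(m0>beta) g(m0)]`,
#' and the delayed-phase analogues in which a word recalled
#' immediately carries strength `gamma * c * m0` into the delayed test
#' while any other word carries `gamma * m0`. Integrals use composite
#' Gauss-Legendre quadrature split at the indicator discontinuities
#' `beta`, `beta/gamma` and `beta/(gamma c)`, with panel doubling to
#' absolute tolerance below 1e-6 per performance measure.
#'
#' @inheritParams encoding_distribution
#' @param design a [task_design()].
#' @return Named numeric vector `pm1`..`pm8`: expected correct recalls
#'   of positive/negative/neutral words and expected errors, at
#'   immediate and delayed recall.
#' @examples
#' expected_pm(recall_params())
#' @export
expected_pm <- function(params, design = task_design(),
                        variant = c("multiplicative", "additive")) {
  variant <- match.arg(variant)
  validate_params(unclass(params)[param_names()], enforce_ranges = FALSE)
  nv <- design$n_per_valence
  pm <- expected_pms_cpp(as.numeric(params[param_names()]),
                         nv[["positive"]], nv[["negative"]], nv[["neutral"]],
                         design$m50, as.integer(variant == "additive"))
  names(pm) <- pm_names()
  pm
}

# batch version over a matrix with columns param_names()
expected_pm_matrix <- function(theta, design = task_design(),
                               variant = "multiplicative") {
  nv <- design$n_per_valence
  pm <- expected_pms_batch_cpp(theta[, param_names(), drop = FALSE],
                               nv[["positive"]], nv[["negative"]],
                               nv[["neutral"]], design$m50,
                               as.integer(variant == "additive"))
  colnames(pm) <- pm_names()
  pm
}

#' Stochastic simulation of one subject's recall session
#'
#' Draws an initial strength per word from [encoding_distribution()],
#' applies the attempt rule (`m0 > beta`), the logistic success rule,
#' the repetition boost `c` for words written down at immediate
#' recall, the forgetting multiplier `gamma`, and the same
#' attempt/success rule at delayed recall. Every attempted-but-failed
#' recall produces exactly one confabulative error.
#'
#' @inheritParams expected_pm
#' @param seed integer seed; mandatory so every simulated subject is
#'   reproducible.
#' @return List with `pm` (integer `pm1`..`pm8`) and `traces`, a
#'   data.frame with one row per studied word (valence, series, m0,
#'   immediate/delayed outcome flags, delayed strength).
#' @examples
#' simulate_subject(recall_params(), seed = 1)$pm
#' @export
simulate_subject <- function(params, design = task_design(), seed,
                             variant = c("multiplicative", "additive")) {
  if (missing(seed)) stop("'seed' is mandatory")
  variant <- match.arg(variant)
  valence <- word_valence_sequence(design)
  n <- length(valence)
  series <- rep(seq_len(design$n_series), each = design$words_per_series)
  eps <- c(neutral = 1, positive = unname(params["eps_pos"]),
           negative = unname(params["eps_neg"]))[valence]
  out <- with_seed(seed, {
    noise <- stats::rnorm(n, 0, unname(params["sigma"]))
    m0 <- if (variant == "additive") eps * unname(params["alpha"]) + noise
          else eps * (unname(params["alpha"]) + noise)
    u1 <- stats::runif(n)
    u2 <- stats::runif(n)
    list(m0 = m0, u1 = u1, u2 = u2)
  })
  m0 <- out$m0
  beta <- unname(params["beta"])
  g <- recall_probability(m0, unname(params["s"]), design$m50)
  attempted <- m0 > beta
  recalled <- attempted & out$u1 < g
  errored <- attempted & !recalled
  m_del <- unname(params["gamma"]) * m0 * ifelse(recalled, unname(params["c"]), 1)
  g_del <- recall_probability(m_del, unname(params["s"]), design$m50)
  attempted_del <- m_del > beta
  recalled_del <- attempted_del & out$u2 < g_del
  errored_del <- attempted_del & !recalled_del
  pm <- c(
    sum(recalled & valence == "positive"),
    sum(recalled & valence == "negative"),
    sum(recalled & valence == "neutral"),
    sum(errored),
    sum(recalled_del & valence == "positive"),
    sum(recalled_del & valence == "negative"),
    sum(recalled_del & valence == "neutral"),
    sum(errored_del)
  )
  names(pm) <- pm_names()
  traces <- data.frame(
    word = seq_len(n), series = series, valence = valence, m0 = m0,
    recalled_immediate = recalled, errored_immediate = errored,
    m_delayed = m_del,
    recalled_delayed = recalled_del, errored_delayed = errored_del,
    stringsAsFactors = FALSE
  )
  list(pm = pm, traces = traces)
}

#' Monte-Carlo estimate of the expected performance measures
#'
#' Averages the eight performance measures over many stochastic
#' sessions of one parameter set. Serves as the independent control
#' for [expected_pm()]: with 1e5 draws the two agree to within
#' Monte-Carlo error.
#'
#' @inheritParams simulate_subject
#' @param n_sim number of simulated sessions.
#' @return List with `mean` (named, `pm1`..`pm8`) and `se`
#'   (Monte-Carlo standard errors of the means).
#' @export
mc_expected_pm <- function(params, design = task_design(), n_sim = 1e5, seed,
                           variant = c("multiplicative", "additive")) {
  if (missing(seed)) stop("'seed' is mandatory")
  variant <- match.arg(variant)
  valence <- word_valence_sequence(design)
  n <- length(valence)
  eps <- c(neutral = 1, positive = unname(params["eps_pos"]),
           negative = unname(params["eps_neg"]))[valence]
  alpha <- unname(params["alpha"]); beta <- unname(params["beta"])
  gamma <- unname(params["gamma"]); sigma <- unname(params["sigma"])
  cc <- unname(params["c"]); s <- unname(params["s"])
  pmsum <- matrix(0, n_sim, 8)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n_sim * n, 0, sigma), n_sim, n)
    m0 <- if (variant == "additive")
      sweep(noise, 2, eps * alpha, "+")
    else
      sweep(noise + alpha, 2, eps, "*")
    g <- 1 / (1 + exp(-s * (m0 - design$m50)))
    attempted <- m0 > beta
    recalled <- attempted & matrix(stats::runif(n_sim * n), n_sim, n) < g
    errored <- attempted & !recalled
    m_del <- gamma * m0 * ifelse(recalled, cc, 1)
    g_del <- 1 / (1 + exp(-s * (m_del - design$m50)))
    att_del <- m_del > beta
    rec_del <- att_del & matrix(stats::runif(n_sim * n), n_sim, n) < g_del
    err_del <- att_del & !rec_del
    for (v in c("positive", "negative", "neutral")) {
      j <- valence == v
      k <- match(v, c("positive", "negative", "neutral"))
      pmsum[, k] <- rowSums(recalled[, j, drop = FALSE])
      pmsum[, 4 + k] <- rowSums(rec_del[, j, drop = FALSE])
    }
    pmsum[, 4] <- rowSums(errored)
    pmsum[, 8] <- rowSums(err_del)
  })
  m <- colMeans(pmsum)
  se <- apply(pmsum, 2, stats::sd) / sqrt(n_sim)
  names(m) <- names(se) <- pm_names()
  list(mean = m, se = se)
}

# valence label per studied word honouring the per-series cap
word_valence_sequence <- function(design) {
  counts <- series_valence_counts(design)
  unlist(lapply(seq_len(design$n_series), function(i) {
    rep(c("neutral", "positive", "negative"), counts[i, ])
  }), use.names = FALSE)
}

# per-series valence counts: rows sum to words_per_series, columns sum
# to n_per_valence, entries capped at max_per_valence_per_series.
# Greedy one-slot-at-a-time from the valence with most words left.
series_valence_counts <- function(design) {
  remaining <- design$n_per_valence
  rows <- matrix(0L, design$n_series, 3,
                 dimnames = list(NULL, names(remaining)))
  for (i in seq_len(design$n_series)) {
    for (slot in seq_len(design$words_per_series)) {
      ok <- remaining > 0 & rows[i, ] < design$max_per_valence_per_series
      if (!any(ok)) stop("cannot satisfy per-series valence cap")
      v <- which(ok)[which.max(remaining[ok])]
      rows[i, v] <- rows[i, v] + 1L
      remaining[v] <- remaining[v] - 1L
    }
  }
  if (any(remaining != 0L)) stop("cannot satisfy per-series valence cap")
  rows
}

# evaluate expr with a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
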