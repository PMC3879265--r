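#' Score typed free-recall responses against a study list
#'
#' A response counts as a successful recall of a target word iff it
#' is spelled exactly, or differs by a single-letter typo (Levenshtein
#' distance 1) that does not turn it into a different valid word of
#' the lexicon (study list plus optional dictionary). Each target can
#' be matched at most once; responses matching no target are
#' confabulative errors. Transpositions count as distance 2 and fail
#' (switch `transpositions = TRUE` for Damerau-style scoring).
#'
#' @param targets character vector of study-list words.
#' @param responses character vector of typed responses.
#' @param lexicon extra valid words beyond the targets (a dictionary).
#' @param transpositions whether adjacent transpositions count as a
#'   single typo.
#' @return Integer vector along `responses`: index of the matched
#'   target, or `NA` for an error.
#' @examples
#' score_recall(c("poverty", "angle"), c("poverty", "anglee", "happy"))
#' @export
score_recall <- function(targets, responses, lexicon = character(),
                         transpositions = FALSE) {
  targets <- tolower(targets)
  responses <- tolower(responses)
  lexicon <- union(tolower(lexicon), targets)
  matched <- rep(NA_integer_, length(responses))
  used <- logical(length(targets))
  if (!length(responses)) return(matched)
  d <- utils::adist(responses, targets)
  if (transpositions) {
    # count an adjacent transposition as one edit
    for (i in seq_along(responses))
      for (j in seq_along(targets))
        if (d[i, j] == 2 && is_transposition(responses[i], targets[j]))
          d[i, j] <- 1
  }
  # exact matches first, then single-typo matches
  for (pass in 0:1) {
    for (i in seq_along(responses)) {
      if (!is.na(matched[i])) next
      hit <- which(d[i, ] == pass & !used)
      if (!length(hit)) next
      if (pass == 1 && responses[i] %in% setdiff(lexicon, targets[hit[1]]))
        next  # the typo produced a different valid word
      matched[i] <- hit[1]
      used[hit[1]] <- TRUE
    }
  }
  matched
}

is_transposition <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diff <- which(ca != cb)
  length(diff) == 2 && diff[2] == diff[1] + 1 &&
    ca[diff[1]] == cb[diff[2]] && ca[diff[2]] == cb[diff[1]]
}

#' Performance measures from a raw recall log
#'
#' Applies the scoring rule to the typed responses of one subject and
#' tallies the eight performance measures: correct recalls per
#' valence and confabulative errors, at immediate (scored per study
#' series) and delayed recall (scored against the whole list).
#'
#' @param study_list data.frame with columns `word`, `valence`
#'   (neutral/positive/negative) and `series`.
#' @param responses data.frame with columns `phase` ("immediate" or
#'   "delayed"), `series` (used for immediate responses) and
#'   `response`.
#' @param design a [task_design()] (validates the list shape).
#' @param lexicon optional dictionary for the different-valid-word
#'   rule.
#' @return Named numeric vector `pm1`..`pm8`.
#' @export
compute_performance_measures <- function(study_list, responses,
                                         design = task_design(),
                                         lexicon = character()) {
  need <- c("word", "valence", "series")
  if (!all(need %in% names(study_list)))
    stop("study_list needs columns ", paste(need, collapse = ", "))
  if (!all(c("phase", "series", "response") %in% names(responses)))
    stop("responses need columns phase, series, response")
  bad <- which(!responses$phase %in% c("immediate", "delayed"))
  if (length(bad))
    stop("malformed log: unknown phase at row ", bad[1])
  if (nrow(study_list) != sum(design$n_per_valence))
    stop("study list does not match the task design word count")

  tally <- function(words, valences, resp) {
    m <- score_recall(words, resp, lexicon = lexicon)
    ok <- !is.na(m)
    c(positive = sum(valences[m[ok]] == "positive"),
      negative = sum(valences[m[ok]] == "negative"),
      neutral = sum(valences[m[ok]] == "neutral"),
      error = sum(!ok))
  }
  imm <- c(positive = 0, negative = 0, neutral = 0, error = 0)
  for (k in unique(study_list$series)) {
    lw <- study_list[study_list$series == k, ]
    rs <- responses$response[responses$phase == "immediate" &
                               responses$series == k]
    imm <- imm + tally(lw$word, lw$valence, rs)
  }
  del <- tally(study_list$word, study_list$valence,
               responses$response[responses$phase == "delayed"])
  stats::setNames(c(imm[c("positive", "negative", "neutral", "error")],
                    del[c("positive", "negative", "neutral", "error")]),
                  pm_names())
}

#' Emotional memory contrast
#'
#' Difference in recall (counts or proportions) between two valence
#' categories; the picture-task phenotype "negative minus neutral
#' proportion recalled" is `emotional_contrast(x)` with the defaults.
#'
#' @param x named numeric vector (or list) of per-valence recall
#'   values.
#' @param valence_a,valence_b categories to contrast (`a - b`).
#' @return `x[valence_a] - x[valence_b]`.
#' @examples
#' emotional_contrast(c(negative = 0.443, neutral = 0.280))
#' @export
emotional_contrast <- function(x, valence_a = "negative",
                               valence_b = "neutral") {
  x <- unlist(x)
  if (!all(c(valence_a, valence_b) %in% names(x)))
    stop("both valence categories must be present")
  unname(x[valence_a] - x[valence_b])
}

#' Principal component analysis of the performance measures
#'
#' Correlation-matrix PCA (measures are z-scored, since counts and
#' error tallies live on different scales) of the subjects x 8 PM
#' table. Components are ordered by explained variance.
#'
#' @param pm_table data.frame/matrix with columns `pm1`..`pm8`.
#' @param var_floor variance floor applied to near-constant measures
#'   (with a warning) so scaling never divides by zero.
#' @return List of class `pm_pca`: `loadings` (8 x 8 orthonormal),
#'   `variance_fraction` (sums to 1), `scores` (subjects x 8).
#' @export
pca_performance <- function(pm_table, var_floor = 1e-12) {
  pm <- as.matrix(pm_table[, pm_names(), drop = FALSE])
  if (nrow(pm) < 9) stop("need at least 9 subjects for an 8-variable PCA")
  if (any(!is.finite(pm))) stop("non-finite performance measures")
  sds <- apply(pm, 2, stats::sd)
  if (any(sds^2 < var_floor)) {
    warning("near-constant performance measure(s): ",
            paste(pm_names()[sds^2 < var_floor], collapse = ", "),
            "; variance floor applied")
    sds <- pmax(sds, sqrt(var_floor))
  }
  z <- scale(pm, center = TRUE, scale = sds)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  structure(list(loadings = pc$rotation,
                 variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 scores = pc$x),
            class = "pm_pca")
}

#' @exportS3Method
print.pm_pca <- function(x, ...) {
  vf <- x$variance_fraction
  cat("PCA of performance measures\n")
  cat("  variance fractions:",
      paste(sprintf("%.1f%%", 100 * vf), collapse = " "), "\n")
  cat(sprintf("  first five components explain %.1f%% of variance\n",
              100 * sum(vf[1:5])))
  invisible(x)
}

#' Lilliefors-type normality screen
#'
#' Kolmogorov-Smirnov test of normality with estimated mean and
#' standard deviation; because the parameters are estimated, the null
#' distribution of the statistic is obtained by Monte-Carlo
#' simulation (seeded, default 1e4 resamples) rather than table
#' lookup. A p-value below 0.05 recommends rank-based (Spearman)
#' association for that phenotype.
#'
#' @param values numeric sample (n >= 20).
#' @param n_mc number of Monte-Carlo null resamples.
#' @param seed integer seed.
#' @return List with `statistic` (the Lilliefors D), `p_value` and
#'   `recommendation` ("spearman" or "pearson").
#' @export
normality_screen <- function(values, n_mc = 1e4, seed = 1) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20) stop("need at least 20 observations")
  D <- lilliefors_statistic(values)
  null <- with_seed(seed, {
    vapply(seq_len(n_mc),
           function(i) lilliefors_statistic(stats::rnorm(n)), numeric(1))
  })
  p <- (1 + sum(null >= D)) / (n_mc + 1)
  list(statistic = D, p_value = p,
       recommendation = if (p < 0.05) "spearman" else "pearson")
}

# KS distance between the empirical cdf and the fitted normal
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}
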