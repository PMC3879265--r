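#' Free-recall task design
#'
#' Describes the verbal task: six series of five nouns, ten words per
#' emotional valence (neutral, positive, negative), at most three
#' words of one valence within a series, and the sigmoid centre
#' constant `m50 = 1` that anchors the memory-strength scale.
#'
#' @param n_series number of study series.
#' @param words_per_series words shown per series.
#' @param n_per_valence named counts for `neutral`, `positive`,
#'   `negative` words (must sum to `n_series * words_per_series`).
#' @param max_per_valence_per_series cap on same-valence words within
#'   one series.
#' @param m50 memory strength at which recall success probability is
#'   exactly 1/2; any positive constant gives an equivalent model
#'   after proportional rescaling of `alpha`, `beta`, `sigma` and
#'   `1/s`.
#' @return Object of class `task_design`.
#' @examples
#' task_design()
#' @export
task_design <- function(n_series = 6, words_per_series = 5,
                        n_per_valence = c(neutral = 10, positive = 10,
                                          negative = 10),
                        max_per_valence_per_series = 3, m50 = 1) {
  if (!setequal(names(n_per_valence), c("neutral", "positive", "negative")))
    stop("'n_per_valence' must be named neutral, positive, negative")
  n_per_valence <- n_per_valence[c("neutral", "positive", "negative")]
  if (n_series * words_per_series != sum(n_per_valence))
    stop("n_series * words_per_series must equal total word count")
  if (max_per_valence_per_series > words_per_series)
    stop("max_per_valence_per_series cannot exceed words_per_series")
  if (m50 <= 0) stop("m50 must be positive")
  structure(list(n_series = n_series, words_per_series = words_per_series,
                 n_per_valence = n_per_valence,
                 max_per_valence_per_series = max_per_valence_per_series,
                 m50 = m50),
            class = "task_design")
}

#' @exportS3Method
print.task_design <- function(x, ...) {
  cat(sprintf("Free-recall task: %d series x %d words (%s), m50 = %g\n",
              x$n_series, x$words_per_series,
              paste(sprintf("%d %s", x$n_per_valence, names(x$n_per_valence)),
                    collapse = ", "),
              x$m50))
  invisible(x)
}

pm_names <- function() paste0("pm", 1:8)

# map PM slots to valence/phase
pm_layout <- function() {
  data.frame(
    pm = pm_names(),
    phase = rep(c("immediate", "delayed"), each = 4),
    valence = rep(c("positive", "negative", "neutral", "error"), 2),
    stringsAsFactors = FALSE
  )
}
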