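# Synthetic cohorts: HWE genotypes at one causal marker plus null
# markers, genotype-dependent negative emotional modulation, and
# stochastic task simulation producing recall logs and PM tables.

#' Specification of a synthetic cohort
#'
#' The `"table1"` preset reproduces the study conditions of the
#' verbal-task association cohort: 1239 subjects with causal-marker
#' genotype groups of 137 (two effect alleles), 532 (one) and 570
#' (none), per-genotype negative-modulation means 1.20 / 1.14 / 1.08
#' with common within-group sd 0.23 (the group s.e.m. times the
#' square root of the group size), and the remaining parameters drawn
#' near the cohort means of the fitted model (`alpha` 1.93, `beta`
#' 1.27, `c` 1.95, `eps_pos` 1.09) with population-fixed `sigma`,
#' `gamma`, `s`.
#'
#' @param n_subjects cohort size.
#' @param causal_counts genotype counts (dosage 2, 1, 0) for the
#'   causal marker; `NULL` draws genotypes from HWE at
#'   `causal_freq` instead.
#' @param causal_freq effect-allele frequency used when
#'   `causal_counts` is `NULL`.
#' @param eps_neg_means per-dosage-group means of `eps_neg`, named
#'   `"0"`, `"1"`, `"2"`.
#' @param eps_neg_sd common within-group sd of `eps_neg`.
#' @param background named list of `c(mean, sd)` laws for the other
#'   free parameters (truncated to [param_ranges()]).
#' @param fixed_values population-fixed parameter values.
#' @param n_null_markers number of phenotype-independent markers.
#' @param null_freq_range allele-frequency range of null markers.
#' @param sites named proportions of subsample (site) labels.
#' @param seed master seed; per-subject and per-stage seeds are
#'   derived from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1239,
                        causal_counts = c("2" = 137, "1" = 532, "0" = 570),
                        causal_freq = NULL,
                        eps_neg_means = c("0" = 1.08, "1" = 1.14, "2" = 1.20),
                        eps_neg_sd = 0.23,
                        background = list(alpha = c(1.93, 0.45),
                                          beta = c(1.27, 0.35),
                                          c = c(1.95, 0.5),
                                          eps_pos = c(1.09, 0.2)),
                        fixed_values = c(sigma = 0.7, gamma = 0.5,
                                         s = 4.133),
                        n_null_markers = 20,
                        null_freq_range = c(0.1, 0.5),
                        sites = c(Zurich = 0.48, Basel = 0.52),
                        seed = 1) {
  if (missing(causal_counts) && n_subjects != 1239) {
    # fall back to HWE sampling at the allele frequency implied by
    # the default genotype counts: (2*137 + 532) / (2*1239)
    causal_counts <- NULL
    if (is.null(causal_freq)) causal_freq <- 806 / 2478
  }
  if (!is.null(causal_counts)) {
    causal_counts <- causal_counts[c("2", "1", "0")]
    if (sum(causal_counts) != n_subjects)
      stop("causal_counts must sum to n_subjects")
  } else if (is.null(causal_freq) || causal_freq <= 0 || causal_freq >= 1) {
    stop("causal_freq must be in (0, 1) when causal_counts is NULL")
  }
  r <- param_ranges()["eps_neg", ]
  if (any(eps_neg_means < r$lower | eps_neg_means > r$upper))
    stop("eps_neg group means outside the parameter range")
  if (eps_neg_sd < 0) stop("eps_neg_sd must be non-negative")
  structure(list(n_subjects = n_subjects, causal_counts = causal_counts,
                 causal_freq = causal_freq, eps_neg_means = eps_neg_means,
                 eps_neg_sd = eps_neg_sd, background = background,
                 fixed_values = fixed_values,
                 n_null_markers = n_null_markers,
                 null_freq_range = null_freq_range, sites = sites,
                 seed = seed),
            class = "cohort_spec")
}

# counter-based seed split: any subject/stage reproducible in isolation
child_seed <- function(master, stage, counter = 0) {
  stage_code <- sum(utf8ToInt(stage)) %% 1000
  (as.numeric(master) * 100003 + stage_code * 7919 + counter) %% 2147483647
}

#' Generate genotypes for a synthetic cohort
#'
#' The causal marker either follows the exact genotype counts of the
#' spec (assigned in random order) or is drawn from Hardy-Weinberg
#' proportions; null markers are always HWE draws independent of the
#' phenotype.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (defaults to a child of the master seed).
#' @return A [genotype_matrix()] whose first marker, `causal`, is the
#'   phenotype-linked one.
#' @export
generate_genotypes <- function(spec, seed = child_seed(spec$seed, "geno")) {
  n <- spec$n_subjects
  with_seed(seed, {
    causal <- if (!is.null(spec$causal_counts)) {
      sample(rep(c(2L, 1L, 0L), spec$causal_counts))
    } else {
      p <- spec$causal_freq
      sample(0:2, n, replace = TRUE,
             prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    }
    nulls <- if (spec$n_null_markers > 0) {
      freqs <- stats::runif(spec$n_null_markers, spec$null_freq_range[1],
                            spec$null_freq_range[2])
      vapply(freqs, function(p)
        sample(0:2, n, replace = TRUE,
               prob = c((1 - p)^2, 2 * p * (1 - p), p^2)),
        integer(n))
    } else NULL
    d <- cbind(causal = causal, nulls)
    colnames(d) <- c("causal",
                     if (spec$n_null_markers > 0)
                       paste0("null", seq_len(spec$n_null_markers)))
    rownames(d) <- sprintf("subj%04d", seq_len(n))
    genotype_matrix(d)
  })
}

rtrunc_norm <- function(n, mean, sd, lower, upper, max_tries = 1000) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (mass < 1e-6)
    stop("degenerate truncation: almost no mass inside [",
         lower, ", ", upper, "]")
  out <- numeric(0)
  for (i in seq_len(max_tries)) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("rejection sampling failed")
}

#' Generate true cognitive parameters for a synthetic cohort
#'
#' `eps_neg` is drawn from a truncated normal whose mean depends on
#' the causal-marker dosage; the other free parameters come from
#' their background laws; the fixed parameters are constants.
#'
#' @param spec a [cohort_spec()].
#' @param genotypes a [genotype_matrix()] containing the `causal`
#'   marker.
#' @param seed integer seed.
#' @return List of class `synthetic_truth`: `parameters` (data.frame
#'   of true values per subject), `dosage`, `causal_marker`.
#' @export
generate_parameters <- function(spec, genotypes,
                                seed = child_seed(spec$seed, "params")) {
  if (!"causal" %in% colnames(genotypes$dosage))
    stop("genotypes must contain the causal marker")
  dosage <- genotypes$dosage[, "causal"]
  n <- length(dosage)
  r <- param_ranges()
  with_seed(seed, {
    eps_neg <- numeric(n)
    for (k in 0:2) {
      idx <- which(dosage == k)
      eps_neg[idx] <- rtrunc_norm(length(idx),
                                  spec$eps_neg_means[[as.character(k)]],
                                  spec$eps_neg_sd,
                                  r["eps_neg", "lower"],
                                  r["eps_neg", "upper"])
    }
    pars <- data.frame(subject_id = rownames(genotypes$dosage),
                       stringsAsFactors = FALSE)
    defaults <- unclass(recall_params())
    for (p in param_names()) {
      pars[[p]] <- if (p == "eps_neg") eps_neg
      else if (p %in% names(spec$background))
        rtrunc_norm(n, spec$background[[p]][1], spec$background[[p]][2],
                    r[p, "lower"], r[p, "upper"])
      else if (p %in% names(spec$fixed_values))
        rep(unname(spec$fixed_values[[p]]), n)
      else rep(defaults[[p]], n)
    }
    structure(list(parameters = pars, dosage = dosage,
                   causal_marker = "causal"),
              class = "synthetic_truth")
  })
}

#' Generate a complete synthetic cohort
#'
#' Genotypes, true parameters, per-subject stochastic recall sessions
#' (subject seeds derived from the master seed), raw recall logs and
#' the PM table. The logs round-trip exactly through
#' [compute_performance_measures()].
#'
#' @param spec a [cohort_spec()].
#' @param design a [task_design()].
#' @return List of class `synthetic_cohort`: `genotypes`, `truth`,
#'   `pm_table`, `study_list`, `logs` (one data.frame of all typed
#'   responses), `sites` (per-subject site label) and `design`.
#' @export
generate_cohort <- function(spec, design = task_design()) {
  genotypes <- generate_genotypes(spec)
  truth <- generate_parameters(spec, genotypes)
  study_list <- synthetic_study_list(design)
  n <- spec$n_subjects
  sites <- with_seed(child_seed(spec$seed, "sites"), {
    sample(names(spec$sites), n, replace = TRUE, prob = spec$sites)
  })
  pm <- matrix(NA_real_, n, 8, dimnames = list(NULL, pm_names()))
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    th <- as_params(unlist(truth$parameters[i, param_names()]),
                    enforce_ranges = FALSE)
    sim <- simulate_subject(th, design,
                            seed = child_seed(spec$seed, "task", i))
    pm[i, ] <- sim$pm
    logs[[i]] <- traces_to_log(truth$parameters$subject_id[i], sim$traces,
                               study_list)
  }
  pm_table <- data.frame(subject_id = truth$parameters$subject_id, pm,
                         stringsAsFactors = FALSE)
  structure(list(genotypes = genotypes, truth = truth,
                 pm_table = pm_table, study_list = study_list,
                 logs = do.call(rbind, logs), sites = sites,
                 design = design, spec = spec),
            class = "synthetic_cohort")
}

#' @exportS3Method
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d markers, %d log rows\n",
              x$spec$n_subjects, ncol(x$genotypes$dosage), nrow(x$logs)))
  invisible(x)
}

# deterministic word list: distinct tokens per valence; confabulated
# tokens used in logs are kept far (edit distance > 1) from all
# study words so scoring can never cross-match
synthetic_study_list <- function(design) {
  valence <- word_valence_sequence(design)
  counter <- c(neutral = 0L, positive = 0L, negative = 0L)
  words <- character(length(valence))
  for (i in seq_along(valence)) {
    counter[valence[i]] <- counter[valence[i]] + 1L
    words[i] <- sprintf("%sword%02d", substr(valence[i], 1, 3),
                        counter[valence[i]])
  }
  data.frame(word = words, valence = valence,
             series = rep(seq_len(design$n_series),
                          each = design$words_per_series),
             stringsAsFactors = FALSE)
}

# build a typed-response log from simulation traces; confabulative
# errors become distinct out-of-list tokens
traces_to_log <- function(subject_id, traces, study_list) {
  err_token <- function(k) sprintf("zz%03d", k)
  rows <- list()
  k <- 0
  for (s in unique(study_list$series)) {
    tr <- traces[traces$series == s, ]
    words <- study_list$word[study_list$series == s]
    resp <- words[tr$recalled_immediate]
    n_err <- sum(tr$errored_immediate)
    if (n_err > 0) {
      resp <- c(resp, vapply(seq_len(n_err),
                             function(j) err_token(k + j), character(1)))
      k <- k + n_err
    }
    if (length(resp))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_id, phase = "immediate", series = s,
        response = resp, stringsAsFactors = FALSE)
  }
  resp_del <- study_list$word[traces$recalled_delayed]
  n_err <- sum(traces$errored_delayed)
  if (n_err > 0) {
    resp_del <- c(resp_del, vapply(seq_len(n_err),
                                   function(j) err_token(k + j),
                                   character(1)))
  }
  if (length(resp_del))
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = subject_id, phase = "delayed", series = NA_integer_,
      response = resp_del, stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(subject_id = character(), phase = character(),
                      series = integer(), response = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
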