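# Tab-separated I/O for the pipeline's tables, minimal VCF dosage
# reading, and structured configuration files.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

check_numeric_columns <- function(tab, cols, what) {
  for (cl in cols) {
    v <- tab[[cl]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop(sprintf("%s: non-numeric value '%s' at row %d, column %s",
                     what, v[bad[1]], bad[1], cl))
      tab[[cl]] <- conv
    }
    if (any(!is.finite(tab[[cl]]) & !is.na(tab[[cl]])))
      stop(sprintf("%s: non-finite value in column %s", what, cl))
  }
  tab
}

#' Read / write a performance-measure table
#'
#' TSV with header `subject_id`, `pm1`..`pm8`.
#'
#' @param path file path.
#' @return Data.frame with `subject_id` and numeric `pm1`..`pm8`.
#' @export
read_pm_table <- function(path) {
  tab <- read_tsv_checked(path)
  miss <- setdiff(c("subject_id", pm_names()), names(tab))
  if (length(miss))
    stop("PM table missing column(s): ", paste(miss, collapse = ", "))
  tab <- check_numeric_columns(tab, pm_names(), "PM table")
  if (any(is.na(tab[, pm_names()])))
    stop("PM table contains missing values")
  tab[, c("subject_id", pm_names())]
}

#' @rdname read_pm_table
#' @param pm_table data.frame with `subject_id` and `pm1`..`pm8`.
#' @export
write_pm_table <- function(pm_table, path) {
  write_tsv(pm_table[, c("subject_id", pm_names())], path)
}

#' Read / write a genotype dosage matrix
#'
#' TSV with a `sample_id` column and one column per marker holding
#' dosage codes 0/1/2 or NA; an optional sidecar TSV carries marker
#' metadata.
#'
#' @param path dosage TSV path.
#' @param markers_path optional marker metadata TSV (`marker_id`,
#'   `effect_allele`, `other_allele`, ...).
#' @return A [genotype_matrix()].
#' @export
read_dosage_matrix <- function(path, markers_path = NULL) {
  tab <- read_tsv_checked(path)
  if (!"sample_id" %in% names(tab))
    stop("dosage matrix needs a sample_id column")
  marker_cols <- setdiff(names(tab), "sample_id")
  tab <- check_numeric_columns(tab, marker_cols, "dosage matrix")
  d <- as.matrix(tab[, marker_cols, drop = FALSE])
  bad <- which(!(d %in% c(0, 1, 2, NA)))
  if (length(bad))
    stop("invalid dosage code ", d[bad[1]], " (must be 0, 1, 2 or NA)")
  rownames(d) <- tab$sample_id
  markers <- if (!is.null(markers_path)) {
    mt <- read_tsv_checked(markers_path)
    if (!"marker_id" %in% names(mt))
      stop("marker metadata needs a marker_id column")
    mt
  } else NULL
  genotype_matrix(d, markers = markers)
}

#' @rdname read_dosage_matrix
#' @param genotypes a [genotype_matrix()].
#' @export
write_dosage_matrix <- function(genotypes, path, markers_path = NULL) {
  d <- genotypes$dosage
  tab <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(tab, path)
  if (!is.null(markers_path)) write_tsv(genotypes$markers, markers_path)
  invisible(path)
}

#' Dosage matrix from a VCF file
#'
#' Reads the GT field of a (plain-text or bgzipped) VCF and codes
#' each sample x variant as the count of ALT alleles; missing calls
#' become `NA`. Only the GT field is used.
#'
#' @param path VCF path.
#' @return A [genotype_matrix()] with marker metadata from the VCF
#'   fixed fields.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  d <- t(apply(gt, c(1, 2), count_alt))
  if (any(d > 2, na.rm = TRUE)) stop("non-diploid genotype in VCF")
  markers <- data.frame(marker_id = rownames(gt),
                        effect_allele = v@fix[, "ALT"],
                        other_allele = v@fix[, "REF"],
                        chrom = v@fix[, "CHROM"],
                        pos = as.integer(v@fix[, "POS"]),
                        stringsAsFactors = FALSE)
  genotype_matrix(d, markers = markers)
}

#' Read / write fitted-parameter tables
#'
#' TSV with `subject_id`, the eight parameters, `chi2`, `p_fit` and a
#' `pass` flag; the top-10 end-point sets go to a sidecar TSV.
#'
#' @param cohort a [fit_cohort()] result.
#' @param path main results path.
#' @param top_sets_path optional sidecar for the per-subject end-point
#'   sets.
#' @export
write_fit_results <- function(cohort, path, top_sets_path = NULL) {
  tab <- cohort$parameters
  tab$pass <- tab$p_fit > 0.05
  write_tsv(tab, path)
  if (!is.null(top_sets_path)) {
    ts <- do.call(rbind, lapply(seq_along(cohort$fits), function(i) {
      data.frame(subject_id = tab$subject_id[i], rank = seq_len(
        nrow(cohort$fits[[i]]$top_sets)), cohort$fits[[i]]$top_sets,
        stringsAsFactors = FALSE)
    }))
    write_tsv(ts, top_sets_path)
  }
  invisible(path)
}

#' @rdname write_fit_results
#' @export
read_fit_results <- function(path) {
  tab <- read_tsv_checked(path)
  check_numeric_columns(tab, intersect(names(tab),
                                       c(param_names(), "chi2", "p_fit")),
                        "fit results")
}

#' Read / write recall logs and study lists
#'
#' Logs are TSV with `subject_id`, `phase`, `series`, `response`;
#' study lists are TSV with `word`, `valence`, `series`.
#'
#' @param path file path.
#' @export
read_recall_log <- function(path) {
  tab <- read_tsv_checked(path)
  need <- c("subject_id", "phase", "series", "response")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("recall log missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' @rdname read_recall_log
#' @param log data.frame of responses.
#' @export
write_recall_log <- function(log, path) write_tsv(log, path)

#' @rdname read_recall_log
#' @export
read_study_list <- function(path) {
  tab <- read_tsv_checked(path)
  miss <- setdiff(c("word", "valence", "series"), names(tab))
  if (length(miss))
    stop("study list missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' @rdname read_recall_log
#' @param study_list data.frame of study words.
#' @export
write_study_list <- function(study_list, path) write_tsv(study_list, path)

config_defaults <- function() {
  list(preset = "desk", seed = 1,
       qc = list(call_rate_min = 0.95, maf_min = 0.05, hwe_p_min = 0.05),
       fit = list())
}

#' Read a pipeline configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`), detected by extension.
#' Unknown top-level keys are rejected; missing keys fall back to the
#' defaults (preset "desk", seed 1, the standard QC thresholds).
#'
#' @param path config file path.
#' @return List with `preset`, `seed`, `qc`, `fit` (overrides passed
#'   to [fit_config()]).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config extension: .", ext,
         " (use .yaml, .yml or .json)"))
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (!cfg$preset %in% c("paper", "desk"))
    stop("preset must be 'paper' or 'desk'")
  cfg
}
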