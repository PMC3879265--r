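#' Construct a genotype dosage matrix
#'
#' Samples x markers additive dosage codes: the count (0/1/2) of the
#' effect allele, `NA` for missing calls.
#'
#' @param dosage numeric matrix (samples x markers) with values in
#'   0, 1, 2 or `NA`.
#' @param sample_ids,marker_ids row/column identifiers.
#' @param markers optional data.frame of marker metadata (`marker_id`,
#'   `effect_allele`, `other_allele`, optionally `chrom`, `pos`).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            marker_ids = colnames(dosage),
                            markers = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0, 1, 2, NA)))
    stop("dosage codes must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(dosage)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(sample_ids, marker_ids)
  if (is.null(markers))
    markers <- data.frame(marker_id = marker_ids,
                          effect_allele = "A", other_allele = "G",
                          stringsAsFactors = FALSE)
  structure(list(dosage = dosage, markers = markers),
            class = "genotype_matrix")
}

#' @exportS3Method
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d markers (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson chi-square test (1 df) of the observed genotype counts
#' against the proportions `(1-p)^2, 2p(1-p), p^2` implied by the
#' sample allele frequency.
#'
#' @param counts genotype counts `(hom_ref, het, hom_alt)`.
#' @return p-value; monomorphic markers return 1 with a warning.
#' @examples
#' hwe_test(c(63, 93, 37))
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3 || any(counts < 0))
    stop("counts must be (hom_ref, het, hom_alt)")
  n <- sum(counts)
  if (n == 0) stop("no genotyped samples")
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (p == 0 || p == 1) {
    warning("monomorphic marker; HWE p set to 1")
    return(1)
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expected)^2 / expected)
  unname(stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Marker quality control
#'
#' Drops markers with call rate below `call_rate_min`, minor allele
#' frequency below `maf_min`, or Hardy-Weinberg equilibrium p-value
#' below `hwe_p_min`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param call_rate_min,maf_min,hwe_p_min thresholds (defaults 0.95,
#'   0.05, 0.05).
#' @return List with the filtered `genotypes` and a `report`
#'   data.frame (per-marker call rate, MAF, HWE p, kept flag and
#'   failure reasons).
#' @export
qc_filter <- function(genotypes, call_rate_min = 0.95, maf_min = 0.05,
                      hwe_p_min = 0.05) {
  d <- genotypes$dosage
  call_rate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- apply(d, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    suppressWarnings(hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2))))
  })
  reasons <- vapply(seq_len(ncol(d)), function(j) {
    r <- c(if (call_rate[j] < call_rate_min) "call_rate",
           if (is.na(maf[j]) || maf[j] < maf_min) "maf",
           if (is.na(hwe_p[j]) || hwe_p[j] < hwe_p_min) "hwe")
    paste(r, collapse = ",")
  }, character(1))
  keep <- reasons == ""
  report <- data.frame(marker_id = colnames(d), call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, keep = keep,
                       reasons = reasons, row.names = NULL,
                       stringsAsFactors = FALSE)
  filtered <- genotype_matrix(d[, keep, drop = FALSE],
                              markers = genotypes$markers[
                                genotypes$markers$marker_id %in%
                                  colnames(d)[keep], , drop = FALSE])
  list(genotypes = filtered, report = report)
}

#' Spearman rank association of a phenotype with allele dosage
#'
#' Additive genetic model: the phenotype is rank-correlated with the
#' 0/1/2 effect-allele count. Ties get average ranks; the p-value
#' uses the t approximation (`stats::cor.test`, `exact = FALSE`).
#' Missing dosages or phenotypes are dropped pairwise.
#'
#' @param phenotype per-sample numeric phenotype.
#' @param dosage per-sample dosage codes.
#' @return List with `rho`, `p_nominal`, `n` and a `degenerate` flag
#'   (TRUE when either variable is constant, in which case `rho` and
#'   `p_nominal` are `NA`).
#' @export
spearman_association <- function(phenotype, dosage) {
  ok <- is.finite(phenotype) & !is.na(dosage)
  x <- phenotype[ok]; g <- dosage[ok]
  if (length(x) < 10) stop("need at least 10 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(g) == 0)
    return(list(rho = NA_real_, p_nominal = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, g, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_nominal = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Bonferroni family-wise correction
#'
#' @param p_nominal nominal p-value(s).
#' @param n_tests number of tests performed (e.g. the post-QC marker
#'   count).
#' @return `min(1, p_nominal * n_tests)`.
#' @examples
#' bonferroni(5.5e-8, 587111)
#' @export
bonferroni <- function(p_nominal, n_tests) {
  if (any(n_tests < 1)) stop("'n_tests' must be >= 1")
  pmin(1, p_nominal * n_tests)
}

#' Per-genotype phenotype summary
#'
#' Sample size, mean and standard error of the phenotype within each
#' dosage group (0/1/2 copies of the effect allele) - the layout of a
#' genotype association table.
#'
#' @inheritParams spearman_association
#' @return Data.frame with columns `dosage`, `n`, `mean`, `sem`.
#' @export
genotype_summary <- function(phenotype, dosage) {
  ok <- is.finite(phenotype) & !is.na(dosage)
  x <- phenotype[ok]; g <- dosage[ok]
  out <- lapply(0:2, function(k) {
    v <- x[g == k]
    data.frame(dosage = k, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else if (length(v) == 1) 0 else NA_real_)
  })
  do.call(rbind, out)
}

#' Association of one marker with one phenotype
#'
#' Bundles [spearman_association()], [bonferroni()] and
#' [genotype_summary()] into one record.
#'
#' @inheritParams spearman_association
#' @param marker_id identifier for the report.
#' @param n_tests number of tests for the Bonferroni correction.
#' @return List of class `association_result`.
#' @export
associate_marker <- function(phenotype, dosage, marker_id = "marker",
                             n_tests = 1) {
  sp <- spearman_association(phenotype, dosage)
  structure(list(marker_id = marker_id, n = sp$n, rho = sp$rho,
                 p_nominal = sp$p_nominal,
                 p_bonferroni = if (is.na(sp$p_nominal)) NA_real_
                                else bonferroni(sp$p_nominal, n_tests),
                 degenerate = sp$degenerate,
                 by_genotype = genotype_summary(phenotype, dosage)),
            class = "association_result")
}

#' @exportS3Method
print.association_result <- function(x, ...) {
  cat(sprintf("%s: rho = %.3f, P_nominal = %.3g, P_Bonferroni = %.3g (n = %d)\n",
              x$marker_id, x$rho, x$p_nominal, x$p_bonferroni, x$n))
  print(x$by_genotype, row.names = FALSE)
  invisible(x)
}

#' Phenotype-wide association scan over all markers
#'
#' Runs [spearman_association()] for every marker of a (QC-filtered)
#' genotype matrix against one phenotype, with Bonferroni correction
#' over the number of markers actually tested.
#'
#' @param phenotype per-sample phenotype, aligned with the rows of
#'   the dosage matrix.
#' @param genotypes a [genotype_matrix()].
#' @param n_tests number of tests for the correction; defaults to the
#'   marker count of `genotypes`.
#' @return Data.frame sorted by nominal p-value: `marker_id`, `n`,
#'   `rho`, `p_nominal`, `p_bonferroni`.
#' @export
association_scan <- function(phenotype, genotypes,
                             n_tests = ncol(genotypes$dosage)) {
  d <- genotypes$dosage
  if (length(phenotype) != nrow(d))
    stop("phenotype length must match the number of samples")
  rows <- lapply(seq_len(ncol(d)), function(j) {
    sp <- spearman_association(phenotype, d[, j])
    data.frame(marker_id = colnames(d)[j], n = sp$n, rho = sp$rho,
               p_nominal = sp$p_nominal,
               p_bonferroni = if (is.na(sp$p_nominal)) NA_real_
                              else bonferroni(sp$p_nominal, n_tests),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_nominal), ]
}

#' Per-subsample association consistency
#'
#' Runs the Spearman association separately within each subsample
#' (e.g. recruitment site) and pooled, and reports whether the
#' correlation signs agree.
#'
#' @inheritParams spearman_association
#' @param labels per-sample subsample tags (>= 2 distinct).
#' @param marker_id identifier for the report.
#' @return List with `pooled`, `by_subsample` (data.frame) and
#'   `sign_agreement`.
#' @export
subsample_consistency <- function(phenotype, dosage, labels,
                                  marker_id = "marker") {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 subsample labels")
  pooled <- spearman_association(phenotype, dosage)
  per <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    sp <- spearman_association(phenotype[labels == l], dosage[labels == l])
    data.frame(subsample = l, n = sp$n, rho = sp$rho,
               p_nominal = sp$p_nominal, stringsAsFactors = FALSE)
  }))
  list(marker_id = marker_id, pooled = pooled, by_subsample = per,
       sign_agreement = length(unique(sign(stats::na.omit(per$rho)))) <= 1)
}
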