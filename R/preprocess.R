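# Beta/M transforms, probe exclusion rules, low-variability filter.

#' Convert beta values to M values
#'
#' M = log2(b / (1 - b)) with b clamped to `[epsilon, 1 - epsilon]` so the
#' transform stays finite at fully (un)methylated probes.
#'
#' @param beta Numeric value, vector or matrix in `[0, 1]`.
#' @param epsilon Clamp bound, `0 < epsilon < 0.5`. Default `1e-6`.
#' @return M values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must be in (0, 0.5)")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M values back to beta values
#'
#' Inverse logit2: beta = 2^M / (1 + 2^M). Round-trips [beta_to_m()]
#' exactly inside the clamp region.
#'
#' @param m Numeric value, vector or matrix of M values.
#' @return Beta values in `[0, 1]`, same shape as `m`.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m) & !is.na(m))) stop("M values must be finite")
  1 / (1 + 2^(-m))
}

#' Assemble a methylation matrix
#'
#' Binds a probes-by-samples beta matrix to its probe annotation and
#' sample metadata, aligning the matrix rows to the (chrom, pos) order of
#' the probe table and deriving the M-value matrix.
#'
#' @param beta Numeric matrix in `[0, 1]`, rownames = probe ids,
#'   colnames = sample ids.
#' @param probes A `probe_table` covering exactly the matrix rows.
#' @param samples Data frame with columns `sample_id`, `group`, `sex`,
#'   `site`, `is_cell_line` (one row per matrix column).
#' @param detection_p Optional matrix of per-entry detection p-values,
#'   same dimensions as `beta`.
#' @param epsilon Clamp bound for the beta-to-M transform.
#' @return A list of class `methylation_matrix` with elements `beta`,
#'   `m`, `detection_p`, `probes`, `samples`.
#' @export
methylation_matrix <- function(beta, probes, samples, detection_p = NULL,
                               epsilon = 1e-6) {
  stopifnot(inherits(probes, "probe_table"), is.matrix(beta))
  if (!setequal(rownames(beta), probes$probe_id))
    stop("beta rownames must match the probe table's probe ids")
  if (!identical(sort(colnames(beta)), sort(samples$sample_id)))
    stop("beta colnames must match samples$sample_id")
  beta <- beta[probes$probe_id, samples$sample_id, drop = FALSE]
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p must have the same dimensions as beta")
    detection_p <- detection_p[probes$probe_id, samples$sample_id,
                               drop = FALSE]
  }
  out <- list(beta = beta,
              m = beta_to_m(beta, epsilon),
              detection_p = detection_p,
              probes = probes,
              samples = samples)
  class(out) <- "methylation_matrix"
  out
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix:", nrow(x$beta), "probes x", ncol(x$beta),
      "samples\n")
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = " "), "\n")
  invisible(x)
}

subset_probes <- function(mat, keep_ids) {
  keep <- mat$probes$probe_id %in% keep_ids
  out <- list(beta = mat$beta[keep, , drop = FALSE],
              m = mat$m[keep, , drop = FALSE],
              detection_p = if (is.null(mat$detection_p)) NULL else
                mat$detection_p[keep, , drop = FALSE],
              probes = mat$probes[keep, , drop = FALSE],
              samples = mat$samples)
  class(out$probes) <- class(mat$probes)
  class(out) <- "methylation_matrix"
  out
}

subset_samples <- function(mat, sample_ids) {
  keep <- mat$samples$sample_id %in% sample_ids
  out <- list(beta = mat$beta[, keep, drop = FALSE],
              m = mat$m[, keep, drop = FALSE],
              detection_p = if (is.null(mat$detection_p)) NULL else
                mat$detection_p[, keep, drop = FALSE],
              probes = mat$probes,
              samples = mat$samples[keep, , drop = FALSE])
  class(out) <- "methylation_matrix"
  out
}

#' Apply the probe-exclusion rules
#'
#' Excludes (a) probes not reliably detected — detection p below
#' `detect_p_thresh` in fewer than `detect_frac` of samples; (b)
#' cross-hybridizing probes; (c) probes with a SNP at or within
#' `snp_dist_max` bp of the target CpG at allele frequency >=
#' `snp_maf_min`. The exclusion reasons may overlap; the remaining matrix
#' preserves genomic order. When no detection p-values are present the
#' detection rule is skipped with a notice.
#'
#' @param mat A `methylation_matrix`.
#' @param crosshyb Character vector of cross-hybridizing probe ids.
#' @param snps Data frame (`probe_id`, `distance_bp`, `allele_freq`) of
#'   SNP records near target CpGs; `NULL` to skip.
#' @param detect_p_thresh Detection p-value cutoff (default 0.01).
#' @param detect_frac Required detected fraction of samples (default 0.95).
#' @param snp_dist_max Maximal SNP distance in bp (default 10).
#' @param snp_maf_min Minimal SNP allele frequency (default 0.05).
#' @return List with elements `matrix` (filtered `methylation_matrix`) and
#'   `report` (class `filter_report`: input/excluded/valid counts and
#'   per-reason id sets).
#' @export
filter_probes <- function(mat, crosshyb = character(), snps = NULL,
                          detect_p_thresh = 0.01, detect_frac = 0.95,
                          snp_dist_max = 10, snp_maf_min = 0.05) {
  stopifnot(inherits(mat, "methylation_matrix"))
  ids <- mat$probes$probe_id

  if (is.null(mat$detection_p)) {
    message("no detection p-values present; detection filter skipped")
    excl_detect <- character()
  } else {
    detected_frac <- rowMeans(mat$detection_p < detect_p_thresh)
    excl_detect <- ids[detected_frac < detect_frac]
  }

  unknown <- setdiff(crosshyb, ids)
  if (length(unknown) > 0L)
    message(length(unknown),
            " cross-hybridizing probe id(s) absent from matrix; ignored")
  excl_xhyb <- intersect(crosshyb, ids)

  excl_snp <- character()
  if (!is.null(snps) && nrow(snps) > 0L) {
    stopifnot(all(c("probe_id", "distance_bp", "allele_freq") %in%
                    names(snps)))
    if (any(snps$distance_bp < 0)) stop("SNP distances must be >= 0")
    if (any(snps$allele_freq < 0 | snps$allele_freq > 1))
      stop("SNP allele frequencies must lie in [0, 1]")
    hit <- snps$distance_bp <= snp_dist_max & snps$allele_freq >= snp_maf_min
    snp_ids <- unique(snps$probe_id[hit])
    unknown_snp <- setdiff(snp_ids, ids)
    if (length(unknown_snp) > 0L)
      message(length(unknown_snp),
              " SNP-affected probe id(s) absent from matrix; ignored")
    excl_snp <- intersect(snp_ids, ids)
  }

  excluded <- union(union(excl_detect, excl_xhyb), excl_snp)
  keep <- setdiff(ids, excluded)
  report <- list(n_input = length(ids),
                 n_excluded_detection = length(excl_detect),
                 n_excluded_crosshyb = length(excl_xhyb),
                 n_excluded_snp = length(excl_snp),
                 n_valid = length(keep),
                 excluded_ids = list(detection = excl_detect,
                                     crosshyb = excl_xhyb,
                                     snp = excl_snp))
  class(report) <- "filter_report"
  list(matrix = subset_probes(mat, keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("probe filter:", x$n_input, "input ->", x$n_valid, "valid",
      sprintf("(detection %d, cross-hyb %d, SNP %d excluded)\n",
              x$n_excluded_detection, x$n_excluded_crosshyb,
              x$n_excluded_snp))
  invisible(x)
}

#' Low-variability feature filter
#'
#' Retains features whose M-value sample standard deviation over all
#' samples is at least `sigma_min` (exclusion is strict `<`). The
#' conventional thresholds are 0.8 for probes and 0.6 for segments.
#'
#' @param m Feature-by-sample numeric matrix of M values (rownames =
#'   feature ids).
#' @param sigma_min Minimal standard deviation to retain a feature.
#' @return Character vector of retained feature ids (in input order).
#' @export
variability_filter <- function(m, sigma_min) {
  if (ncol(m) < 2L)
    stop("variability filter requires at least 2 samples")
  rownames(m)[row_sds(m) >= sigma_min]
}
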