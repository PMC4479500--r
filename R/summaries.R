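# Enrichment of DMP sets over functional/chromosome/state categories,
# imprinting and X-chromosome summaries, global distribution and PCA
# descriptors.

#' Bonferroni-corrected enrichment significance level
#'
#' The family-wise significance level for the enrichment analysis:
#' `alpha / (n_functional + n_chromosomes + n_states)`. With the default
#' family (18 functional categories, 24 chromosomes, 20 HMM states) this
#' is 0.05/62 = 0.00080645161...
#'
#' @param n_functional Number of functional categories (default 18).
#' @param n_chromosomes Number of chromosome categories (default 24).
#' @param n_states Number of HMM-state categories (default 20).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test significance threshold.
#' @export
bonferroni_alpha <- function(n_functional = 18L, n_chromosomes = 24L,
                             n_states = 20L, alpha = 0.05) {
  alpha / (n_functional + n_chromosomes + n_states)
}

#' Default delta-M cutoff
#'
#' The midpoint of the recommended M-value difference cutoff range
#' (0.4-1.4), giving the default `dm_min = 0.9`.
#'
#' @param low,high Bounds of the recommended cutoff range.
#' @return The midpoint.
#' @export
dm_cutoff_midpoint <- function(low = 0.4, high = 1.4) {
  (low + high) / 2
}

#' Per-chromosome probe categories
#'
#' @param probes A `probe_table`.
#' @param chroms Chromosome names to build sets for (default 1-22, X, Y;
#'   chromosomes absent from the probe table yield empty sets).
#' @return Named list `CHR_*` of probe id vectors.
#' @export
chromosome_categories <- function(probes, chroms = CHROM_LEVELS) {
  out <- lapply(chroms, function(ch) probes$probe_id[probes$chrom == ch])
  names(out) <- paste0("CHR_", chroms)
  out
}

#' Per-HMM-state probe categories
#'
#' @param segments An `hmm_segments` object.
#' @return Named list `STATE_*` of probe id vectors, one per model state.
#' @export
state_categories <- function(segments) {
  stopifnot(inherits(segments, "hmm_segments"))
  out <- lapply(seq_len(segments$k), function(s)
    names(segments$probe_state)[segments$probe_state == s])
  names(out) <- paste0("STATE_", seq_len(segments$k))
  out
}

#' Fisher-exact enrichment of a DMP set over probe categories
#'
#' For each category, tests the 2x2 table of (DMP vs non-DMP) x (inside
#' vs outside the category) with a two-sided Fisher exact test (summing
#' all tables with point probability at most that observed).
#' `log2_ratio` is `log2((% of DMPs in the category) / (% of non-DMPs in
#' the category))`; a zero numerator is reported as `NA` while the
#' significance flag is retained. Categories with no members in the
#' universe are skipped with a warning.
#'
#' @param dmp_ids Character vector of DMP probe ids (subset of
#'   `universe`).
#' @param universe All valid probe ids.
#' @param categories Named list of probe id vectors (functional,
#'   per-chromosome and/or per-state sets).
#' @param alpha_bonf Per-test significance threshold; defaults to
#'   `0.05 / length(categories)`. Use [bonferroni_alpha()] to reproduce
#'   the conventional 18+24+20 family.
#' @return Data frame: `category`, the four table counts, `odds_ratio`,
#'   `p_value`, `significant`, `log2_ratio`.
#' @export
fisher_enrichment <- function(dmp_ids, universe, categories,
                              alpha_bonf = NULL) {
  if (!all(dmp_ids %in% universe))
    stop("dmp_ids must be a subset of the universe")
  if (is.null(alpha_bonf)) alpha_bonf <- 0.05 / length(categories)
  is_dmp <- universe %in% dmp_ids
  n_dmp <- sum(is_dmp)
  n_non <- length(universe) - n_dmp
  rows <- lapply(names(categories), function(nm) {
    in_cat <- universe %in% categories[[nm]]
    if (!any(in_cat)) {
      warning("category with no universe members skipped: ", nm)
      return(NULL)
    }
    a <- sum(is_dmp & in_cat)
    b <- n_dmp - a
    c_ <- sum(!is_dmp & in_cat)
    d <- n_non - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, 2L))
    lr <- if (a == 0L || n_dmp == 0L) NA_real_ else
      log2((a / n_dmp) / (c_ / n_non))
    data.frame(category = nm, n_dmp_in = a, n_dmp_out = b,
               n_non_in = c_, n_non_out = d,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               significant = ft$p.value < alpha_bonf, log2_ratio = lr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = character(), n_dmp_in = integer(),
                      n_dmp_out = integer(), n_non_in = integer(),
                      n_non_out = integer(), odds_ratio = numeric(),
                      p_value = numeric(), significant = logical(),
                      log2_ratio = numeric(), stringsAsFactors = FALSE)
  attr(out, "alpha_bonf") <- alpha_bonf
  rownames(out) <- NULL
  out
}

band_label <- function(median_beta, bands = c(0.25, 0.75)) {
  ifelse(median_beta < bands[1L], "erased",
         ifelse(median_beta > bands[2L], "uniparental", "somatic"))
}

#' Imprinting and X-chromosome methylation summary
#'
#' Per group and category (typically `ICR_P`, `ICR_M`, `X_CHROM`),
#' summarizes the pooled beta values of all member probes over the
#' group's samples: quantiles and a qualitative band label. The band
#' cutoffs (erased < 0.25 <= somatic <= 0.75 < uniparental) are a
#' convention of this package for test assertions, not a biological
#' standard, and are recorded in the output.
#'
#' @param mat A `methylation_matrix`.
#' @param categories Named list of probe id vectors.
#' @param groups Optional subset of group labels (default: all).
#' @param bands Band cutoffs on median beta.
#' @return Data frame: `group`, `category`, `n_probes`, `q0`, `q25`,
#'   `median`, `q75`, `q100`, `band`; attribute `bands`.
#' @export
imprinting_summary <- function(mat, categories, groups = NULL,
                               bands = c(0.25, 0.75)) {
  stopifnot(inherits(mat, "methylation_matrix"))
  if (is.null(groups)) groups <- unique(mat$samples$group)
  rows <- list()
  for (g in groups) {
    cols <- mat$samples$sample_id[mat$samples$group == g]
    if (length(cols) == 0L) stop("empty group: ", g)
    for (nm in names(categories)) {
      keep <- mat$probes$probe_id %in% categories[[nm]]
      if (!any(keep)) next
      v <- as.vector(mat$beta[keep, cols, drop = FALSE])
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, category = nm, n_probes = sum(keep),
        q0 = q[1L], q25 = q[2L], median = q[3L], q75 = q[4L], q100 = q[5L],
        band = band_label(q[3L], bands), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bands") <- bands
  out
}

#' PCA separation summary with bootstrap validation
#'
#' Mean-centered principal component analysis of the samples on M values;
#' group separation in the PC1-PC2 plane is scored by the mean silhouette
#' width of the group labels (Euclidean distance on the first two score
#' columns), and validated over `n_boot` stratified bootstrap resamples
#' (PCA and silhouette recomputed per resample). With a single group the
#' silhouette is undefined and reported as `NA`.
#'
#' @param m Feature-by-sample M-value matrix.
#' @param groups Group label per sample (matrix column).
#' @param n_boot Bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return List: `scores` (data frame `sample_id`, `group`, `PC1`,
#'   `PC2`), `silhouette`, `boot_silhouette` (vector),
#'   `mean_boot_silhouette`.
#' @export
pca_summary <- function(m, groups, n_boot = 100L, seed = 1L) {
  stopifnot(is.matrix(m), ncol(m) == length(groups))
  if (ncol(m) < 3L) stop("at least 3 samples required")
  if (nrow(m) < 2L) stop("at least 2 features required")
  groups <- as.factor(as.character(groups))
  if (ncol(m) < nlevels(groups)) stop("fewer samples than groups")

  pc_scores <- function(cols) {
    p <- stats::prcomp(t(m[, cols, drop = FALSE]), center = TRUE,
                       scale. = FALSE, rank. = 2L)
    s <- p$x
    if (ncol(s) < 2L) s <- cbind(s, 0)
    s[, 1:2, drop = FALSE]
  }
  sil <- function(scores, g) {
    g <- as.integer(factor(as.character(g)))
    if (length(unique(g)) < 2L) return(NA_real_)
    mean(cluster::silhouette(g, stats::dist(scores))[, "sil_width"])
  }

  all_cols <- seq_len(ncol(m))
  scores <- pc_scores(all_cols)
  full_sil <- sil(scores, groups)

  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- stratified_resample(groups)
    sil(pc_scores(idx), groups[idx])
  }, numeric(1))

  list(scores = data.frame(sample_id = colnames(m),
                           group = as.character(groups),
                           PC1 = scores[, 1L], PC2 = scores[, 2L],
                           stringsAsFactors = FALSE),
       silhouette = full_sil,
       boot_silhouette = boot,
       mean_boot_silhouette = mean(boot, na.rm = TRUE))
}

#' Group-wise beta distribution summary
#'
#' Pools the beta values of a probe subset per group and summarizes them
#' by quantiles and a Gaussian-kernel density on a grid over `[0, 1]`,
#' renormalized to integrate to one on the grid (trapezoidal rule).
#' Bandwidth defaults to Silverman's rule on the pooled values.
#'
#' @param mat A `methylation_matrix`.
#' @param subset_ids Probe ids to pool (default: all probes).
#' @param groups Optional subset of group labels (default: all).
#' @param bw Kernel bandwidth; `NULL` for Silverman's rule per group.
#' @param n_grid Density grid size (default 512).
#' @return Named list per group: `quantiles` (min/q25/median/q75/max) and
#'   `density` (data frame `x`, `y`).
#' @export
distribution_summary <- function(mat, subset_ids = NULL, groups = NULL,
                                 bw = NULL, n_grid = 512L) {
  stopifnot(inherits(mat, "methylation_matrix"))
  keep <- if (is.null(subset_ids)) rep(TRUE, nrow(mat$beta)) else
    mat$probes$probe_id %in% subset_ids
  if (!any(keep)) stop("probe subset is empty")
  if (is.null(groups)) groups <- unique(mat$samples$group)
  out <- lapply(groups, function(g) {
    cols <- mat$samples$sample_id[mat$samples$group == g]
    v <- as.vector(mat$beta[keep, cols, drop = FALSE])
    d <- stats::density(v, bw = if (is.null(bw)) "nrd0" else bw,
                        from = 0, to = 1, n = n_grid)
    dx <- diff(d$x)
    area <- sum((d$y[-1L] + d$y[-length(d$y)]) / 2 * dx)
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    list(quantiles = c(min = q[1L], q25 = q[2L], median = q[3L],
                       q75 = q[4L], max = q[5L]),
         density = data.frame(x = d$x, y = d$y / area))
  })
  names(out) <- groups
  out
}
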