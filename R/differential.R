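# Three-route differentially methylated probe (DMP) selection:
# per-probe and per-segment Mann-Whitney testing with BH correction,
# stratified-bootstrap stability validation and a |delta median M| cutoff,
# plus logistic-LASSO selection of discriminating HMM states, intersected
# into direction-labelled DMP sets.

# Two-sided Mann-Whitney U p-value for one feature. Exact (via the null
# U distribution) when both groups are small and there are no ties;
# tie-corrected normal approximation with continuity correction otherwise.
mwu_p <- function(x, y, exact_max_n = 12L) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (!has_ties && n1 <= exact_max_n && n2 <= exact_max_n) {
    p <- 2 * stats::pwilcox(min(u, n1 * n2 - u), n1, n2)
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- z - sign(z) * 0.5
  p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  min(1, p)
}

#' Mann-Whitney U tests with Benjamini-Hochberg correction
#'
#' Applies a two-sided Mann-Whitney U test to each feature (matrix row),
#' comparing the two groups given by `labels`, and adjusts the p-values by
#' the Benjamini-Hochberg step-up procedure across all tested features.
#' The exact null distribution is used when both groups have at most
#' `exact_max_n` observations and the feature has no ties; otherwise a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param m Feature-by-sample numeric matrix (rownames = feature ids).
#' @param labels Two-level group assignment, one per column.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @param exact_max_n Largest per-group size for the exact test.
#' @return Data frame `feature_id`, `p_raw`, `p_adj`, `significant`.
#' @export
mwu_bh <- function(m, labels, alpha = 0.05, exact_max_n = 12L) {
  labels <- assert_two_groups(labels)
  stopifnot(is.matrix(m), ncol(m) == length(labels))
  a <- labels == levels(labels)[1L]
  p <- vapply(seq_len(nrow(m)),
              function(i) mwu_p(m[i, a], m[i, !a], exact_max_n),
              numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(m), p_raw = p, p_adj = p_adj,
             significant = p_adj < alpha, stringsAsFactors = FALSE)
}

#' Stratified-bootstrap stability validation
#'
#' For each of `n_boot` replicates, samples are drawn with replacement
#' within each group (preserving group sizes); a feature counts as
#' supported in a replicate iff its Mann-Whitney test is significant at
#' `alpha` after BH adjustment across the candidate set within that
#' replicate (`adjust = "none"` uses raw p-values instead). The support
#' fraction is supported replicates / `n_boot`. Deterministic given
#' `seed`.
#'
#' @param m Feature-by-sample matrix restricted to candidate features
#'   (typically the BH-significant ones on the full data).
#' @param labels Two-level group assignment, one per column.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param alpha Per-replicate significance level (default 0.05).
#' @param seed Integer seed.
#' @param adjust `"BH"` (default) or `"none"`: multiplicity handling
#'   within each replicate.
#' @return Named numeric vector of support fractions in `[0, 1]`.
#' @export
bootstrap_validate <- function(m, labels, n_boot = 100L, alpha = 0.05,
                               seed = 1L, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  labels <- assert_two_groups(labels)
  stopifnot(is.matrix(m), ncol(m) == length(labels))
  if (any(table(labels) < 2L))
    stop("bootstrap requires at least 2 samples per group")
  if (nrow(m) == 0L) return(stats::setNames(numeric(0), character(0)))
  set.seed(as.integer(seed))
  a_lev <- levels(labels)[1L]
  supported <- numeric(nrow(m))
  for (b in seq_len(n_boot)) {
    idx <- stratified_resample(labels)
    lab_b <- labels[idx]
    a <- lab_b == a_lev
    p <- vapply(seq_len(nrow(m)),
                function(i) mwu_p(m[i, idx][a], m[i, idx][!a]),
                numeric(1))
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    supported <- supported + (p < alpha)
  }
  stats::setNames(supported / n_boot, rownames(m))
}

# Full per-feature testing cascade for one feature kind (probes or
# segments): variability filter, MWU+BH, bootstrap of the significant
# features, delta-median-M cutoff and direction call. The variability
# filter may be computed on a wider sample set (`m_filter`, e.g. all
# tumor samples) than the two compared groups.
test_features <- function(m, labels, sigma_min, dm_min = 0.9,
                          alpha = 0.05, n_boot = 100L, support_min = 0.95,
                          seed = 1L, adjust = "BH", m_filter = m) {
  labels <- assert_two_groups(labels)
  stopifnot(identical(rownames(m_filter), rownames(m)))
  retained <- variability_filter(m_filter, sigma_min)
  res <- data.frame(feature_id = rownames(m),
                    sigma = row_sds(m_filter),
                    retained = rownames(m) %in% retained,
                    p_raw = NA_real_, p_adj = NA_real_,
                    support = NA_real_,
                    delta_median_m = NA_real_,
                    direction = "none",
                    passes = FALSE,
                    stringsAsFactors = FALSE)
  rownames(res) <- res$feature_id
  if (length(retained) == 0L) return(res)

  mr <- m[retained, , drop = FALSE]
  tst <- mwu_bh(mr, labels, alpha = alpha)
  res[retained, c("p_raw", "p_adj")] <- tst[, c("p_raw", "p_adj")]

  a <- labels == levels(labels)[1L]
  delta <- apply(mr[, a, drop = FALSE], 1L, stats::median) -
    apply(mr[, !a, drop = FALSE], 1L, stats::median)
  res[retained, "delta_median_m"] <- delta

  cand <- retained[tst$significant]
  if (length(cand) > 0L) {
    supp <- bootstrap_validate(m[cand, , drop = FALSE], labels,
                               n_boot = n_boot, alpha = alpha,
                               seed = seed, adjust = adjust)
    res[cand, "support"] <- supp
    pass <- cand[supp >= support_min &
                   abs(res[cand, "delta_median_m"]) > dm_min]
    res[pass, "passes"] <- TRUE
    res[pass, "direction"] <- ifelse(res[pass, "delta_median_m"] > 0,
                                     "hyperA", "hyperB")
  }
  res
}

#' Probe-route and segment-route differential testing
#'
#' Runs the testing cascade (variability filter, Mann-Whitney + BH,
#' stratified-bootstrap validation at `support_min`, and the
#' `|delta median M| > dm_min` cutoff) on individual probes and on HMM
#' segments (via their per-sample median-M proxies). Passing segments are
#' expanded to their member probes.
#'
#' @param m Probe-by-sample M-value matrix (all probes, genomic order).
#' @param segments An `hmm_segments` object over the same probes.
#' @param labels Two-level group assignment, one per column of `m`.
#' @param sigma_probe,sigma_segment Variability thresholds (defaults 0.8
#'   and 0.6).
#' @param dm_min Minimal absolute difference of group median M values
#'   (default 0.9; exclusion is `<=`).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param n_boot,support_min Bootstrap replicates and required support.
#' @param seed Integer seed for the bootstrap.
#' @param m_filter Optional matrix over a wider sample set (same rows as
#'   `m`, e.g. all tumor samples) on which the variability filter is
#'   computed; defaults to `m` itself.
#' @return List with `probe` and `segment` feature-test data frames and
#'   `segment_probes` (data frame `probe_id`, `direction` of probes in
#'   passing segments).
#' @export
route_probe_and_segment <- function(m, segments, labels,
                                    sigma_probe = 0.8, sigma_segment = 0.6,
                                    dm_min = 0.9, alpha = 0.05,
                                    n_boot = 100L, support_min = 0.95,
                                    seed = 1L, m_filter = m) {
  stopifnot(inherits(segments, "hmm_segments"),
            nrow(m) == length(segments$probe_segment))
  probe_res <- test_features(m, labels, sigma_min = sigma_probe,
                             dm_min = dm_min, alpha = alpha,
                             n_boot = n_boot, support_min = support_min,
                             seed = seed, m_filter = m_filter)
  seg_m <- segment_medians(segments, m)
  seg_res <- test_features(seg_m, labels, sigma_min = sigma_segment,
                           dm_min = dm_min, alpha = alpha,
                           n_boot = n_boot, support_min = support_min,
                           seed = seed + 1L,
                           m_filter = segment_medians(segments, m_filter))
  pass_seg <- seg_res$feature_id[seg_res$passes]
  seg_ids <- segments$table$segment_id[segments$probe_segment]
  in_pass <- seg_ids %in% pass_seg
  segment_probes <- data.frame(
    probe_id = names(segments$probe_segment)[in_pass],
    direction = seg_res[seg_ids[in_pass], "direction"],
    stringsAsFactors = FALSE)
  out <- list(probe = probe_res, segment = seg_res,
              segment_probes = segment_probes)
  attr(out, "universe") <- rownames(m)
  out
}

#' LASSO selection of discriminating HMM states
#'
#' Fits an L1-penalized logistic regression of the two-group label on the
#' per-state median M values (states as predictors, standardized), with
#' `n_folds`-fold cross-validation stratified by group, and selects the
#' states with nonzero coefficient in the most regularized model within
#' one standard error of the minimal cross-validation binomial-deviance
#' error (the 1-SE rule). By default coefficients of either sign are
#' selected, since direction is subsequently assigned by the sign of the
#' per-probe delta median M; `positive_only = TRUE` restricts to strictly
#' positive coefficients.
#'
#' @param state_m State-by-sample median-M matrix (rownames = state ids).
#' @param labels Two-level group assignment, one per column.
#' @param n_folds Cross-validation folds (default 10); reduced with a
#'   warning when a group is smaller than `n_folds`.
#' @param seed Integer seed (fold assignment).
#' @param positive_only Select only strictly positive coefficients.
#' @param nlambda,lambda_min_ratio Lambda path: `nlambda` values
#'   log-spaced down from the null-model lambda by `lambda_min_ratio`.
#' @return List: `selected` (state ids), `coefficients` (named, at the
#'   1-SE lambda), `lambda_min`, `lambda_1se`.
#' @export
lasso_state_selection <- function(state_m, labels, n_folds = 10L,
                                  seed = 1L, positive_only = FALSE,
                                  nlambda = 100L, lambda_min_ratio = 1e-4) {
  labels <- assert_two_groups(labels)
  stopifnot(is.matrix(state_m), ncol(state_m) == length(labels))
  if (nrow(state_m) < 2L) stop("at least 2 states required")
  min_group <- min(table(labels))
  if (min_group < n_folds) {
    n_folds <- max(2L, min_group)
    warning("smallest group below requested fold count; using ",
            n_folds, " folds")
  }
  x <- t(state_m)
  y <- labels
  set.seed(as.integer(seed))
  foldid <- stratified_folds(labels, n_folds)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio,
                          standardize = TRUE,
                          grouped = min(table(foldid)) >= 3L)
  beta <- stats::coef(cv, s = "lambda.1se")[-1L, 1L]
  names(beta) <- rownames(state_m)
  selected <- if (positive_only) names(beta)[beta > 0] else
    names(beta)[beta != 0]
  list(selected = selected, coefficients = beta,
       lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se)
}

#' Intersect the three DMP routes
#'
#' A probe is a DMP iff it passes the per-probe route, lies in a passing
#' segment, and lies in a LASSO-selected state while showing a per-probe
#' `|delta median M| > dm_min` — all in the same direction. The two
#' directions (relative hypermethylation in group A or in group B) are
#' returned separately, with per-probe provenance of the admitting routes.
#'
#' @param routes Result of [route_probe_and_segment()].
#' @param state_selection Result of [lasso_state_selection()].
#' @param segments The `hmm_segments` used for both (provides the
#'   probe-to-state map).
#' @param comparison Character vector `c(group_a, group_b)` recorded in
#'   the output.
#' @param dm_min Minimal per-probe absolute delta median M within the
#'   state route (default 0.9).
#' @return A list of class `dmp_set`: `comparison`, `hyper_a`, `hyper_b`
#'   (probe id vectors) and `provenance` (per-probe route membership).
#' @export
intersect_dmps <- function(routes, state_selection, segments,
                           comparison = c("A", "B"), dm_min = 0.9) {
  stopifnot(inherits(segments, "hmm_segments"))
  universe <- attr(routes, "universe")
  if (!setequal(universe, names(segments$probe_state)))
    stop("routes and segmentation cover different probe universes")
  probe_res <- routes$probe

  sel_states <- state_selection$selected
  in_state <- names(segments$probe_state)[
    as.character(segments$probe_state) %in% sel_states]
  delta <- stats::setNames(probe_res$delta_median_m, probe_res$feature_id)

  pick <- function(dir) {
    sgn <- if (dir == "hyperA") 1 else -1
    probe_pass <- probe_res$feature_id[probe_res$passes &
                                         probe_res$direction == dir]
    seg_pass <- routes$segment_probes$probe_id[
      routes$segment_probes$direction == dir]
    state_pass <- in_state[!is.na(delta[in_state]) &
                             sgn * delta[in_state] > dm_min]
    Reduce(intersect, list(probe_pass, seg_pass, state_pass))
  }
  hyper_a <- pick("hyperA")
  hyper_b <- pick("hyperB")

  members <- union(hyper_a, hyper_b)
  provenance <- data.frame(
    probe_id = members,
    direction = ifelse(members %in% hyper_a, "hyperA", "hyperB"),
    in_probe_route = rep(TRUE, length(members)),
    in_segment_route = rep(TRUE, length(members)),
    in_state_route = rep(TRUE, length(members)),
    state = unname(segments$probe_state[members]),
    delta_median_m = unname(delta[members]),
    stringsAsFactors = FALSE)
  out <- list(comparison = comparison, hyper_a = hyper_a,
              hyper_b = hyper_b, provenance = provenance,
              universe = universe)
  class(out) <- "dmp_set"
  out
}

#' @export
print.dmp_set <- function(x, ...) {
  cat(sprintf("dmp_set %s vs %s: %d hyper-%s, %d hyper-%s (of %d probes)\n",
              x$comparison[1L], x$comparison[2L],
              length(x$hyper_a), x$comparison[1L],
              length(x$hyper_b), x$comparison[2L], length(x$universe)))
  invisible(x)
}
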