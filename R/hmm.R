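# Gaussian-emission HMM segmentation of genomically ordered M-value
# profiles: Baum-Welch training, state-count selection by likelihood
# saturation, Viterbi run-length segments and median-M proxies.
#
# Emissions are diagonal-covariance multivariate Gaussians over the
# per-probe vector of M values across samples. Each chromosome is an
# independent observation sequence sharing one parameter set; transitions
# restart from pi at every chromosome start. Inter-probe genomic distance
# is not modelled.

# Per-probe emission log-density under each state.
# m: T x S observations; means, vars: k x S.
emission_logdens <- function(m, means, vars) {
  iv <- 1 / vars
  const <- -0.5 * (ncol(m) * log(2 * pi) + rowSums(log(vars))) -
    0.5 * rowSums(means^2 * iv)
  out <- -0.5 * (m^2 %*% t(iv)) + m %*% t(means * iv)
  sweep(out, 2L, const, `+`)
}

# D^2-weighted center seeding (k-means++ style); gives rare but extreme
# emission patterns a realistic chance of seeding their own state.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in 2L:k) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

split_sequences <- function(chrom) {
  r <- rle(as.character(chrom))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

em_fit_once <- function(m, seqs, k, tol, max_iter, var_floor) {
  n <- nrow(m)
  s <- ncol(m)
  if (k > 1L) {
    centers <- kmeanspp_centers(m, k)
    km <- suppressWarnings(stats::kmeans(m, centers = centers,
                                         iter.max = 25L))
    means <- km$centers
  } else {
    means <- matrix(colMeans(m), 1L, s)
  }
  v0 <- pmax(apply(m, 2L, stats::var), var_floor)
  vars <- matrix(rep(v0, each = k), k, s)
  pi <- rep(1 / k, k)
  A <- matrix(if (k > 1L) 0.1 / (k - 1L) else 0, k, k)
  diag(A) <- if (k > 1L) 0.9 else 1

  ll_hist <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logB <- emission_logdens(m, means, vars)
    ll <- 0
    gamma <- matrix(0, n, k)
    xi <- matrix(0, k, k)
    pi_num <- numeric(k)
    for (idx in seqs) {
      fb <- forward_backward_cpp(logB[idx, , drop = FALSE], log(pi), log(A))
      ll <- ll + fb$loglik
      gamma[idx, ] <- fb$gamma
      xi <- xi + fb$xi
      pi_num <- pi_num + fb$gamma[1L, ]
    }
    ll_hist <- c(ll_hist, ll)

    pi <- pi_num / length(seqs)
    pi <- pi / sum(pi)
    if (k > 1L) {
      rs <- rowSums(xi)
      A <- xi / ifelse(rs > 0, rs, 1)
      A[rs == 0, ] <- 1 / k
    }
    w <- colSums(gamma)
    live <- w > 1e-8
    if (any(live)) {
      gw <- sweep(gamma[, live, drop = FALSE], 2L, w[live], `/`)
      means[live, ] <- t(gw) %*% m
      vars[live, ] <- pmax(t(gw) %*% m^2 - means[live, , drop = FALSE]^2,
                           var_floor)
    }

    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(k = k, pi = pi, A = A, means = means, vars = vars,
       loglik = ll_hist[length(ll_hist)], loglik_history = ll_hist,
       n_iter = length(ll_hist), converged = converged)
}

#' Fit a k-state Gaussian-emission HMM to ordered M-value profiles
#'
#' Trains the segmentation HMM by Baum-Welch EM on per-probe M-value
#' vectors in genomic order. Each chromosome is treated as an independent
#' observation sequence sharing the single parameter set. Emission means
#' are initialized by D^2-weighted (k-means++ style) seeding followed by
#' k-means; `n_restarts` independent initializations are run and the model
#' with the highest log-likelihood kept. All randomness is governed by
#' `seed`, so refits are reproducible.
#'
#' @param m Probe-by-sample matrix of M values, rows in genomic order.
#' @param chrom Chromosome label per row (defines sequence boundaries).
#' @param k Number of hidden states.
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximal EM iterations per restart.
#' @param n_restarts Number of random restarts; best likelihood kept.
#' @param var_floor Lower bound on emission variances.
#' @return A list of class `hmm_model`: `k`, `pi`, `A`, `means`, `vars`
#'   (k x samples), `loglik`, `loglik_history`, `n_iter`, `converged`,
#'   `seed`, `sample_ids`.
#' @export
fit_hmm <- function(m, chrom, k, seed = 1L, tol = 1e-6, max_iter = 500L,
                    n_restarts = 3L, var_floor = 1e-3) {
  stopifnot(is.matrix(m), length(chrom) == nrow(m))
  if (any(!is.finite(m))) stop("non-finite M values in input matrix")
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(m)) stop("k exceeds the number of probes")
  seqs <- split_sequences(chrom)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    fit <- em_fit_once(m, seqs, k, tol, max_iter, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$seed <- as.integer(seed)
  best$sample_ids <- colnames(m)
  class(best) <- "hmm_model"
  best
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("hmm_model: k =", x$k, "states,", length(x$sample_ids), "samples,",
      "loglik =", format(x$loglik), "\n")
  invisible(x)
}

#' Select the number of HMM states by likelihood saturation
#'
#' Fits the model over an ascending grid of state counts and returns the
#' full log-likelihood curve together with the smallest k whose successor
#' improves the log-likelihood by less than `saturation_frac` (relative to
#' the current magnitude). If no k saturates, the largest grid value is
#' returned.
#'
#' @inheritParams fit_hmm
#' @param k_grid Ascending integer vector of candidate state counts.
#' @param saturation_frac Relative-improvement threshold (default 0.01).
#' @param ... Passed to [fit_hmm()].
#' @return List with `k_selected` and `loglik_curve` (data frame `k`,
#'   `loglik`).
#' @export
select_k <- function(m, chrom, k_grid, seed = 1L, saturation_frac = 0.01,
                     ...) {
  if (length(k_grid) == 0L) stop("k_grid must be non-empty")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k_grid must be ascending")
  ll <- vapply(k_grid, function(k)
    fit_hmm(m, chrom, k, seed = seed, ...)$loglik, numeric(1))
  curve <- data.frame(k = k_grid, loglik = ll)
  k_selected <- k_grid[length(k_grid)]
  if (length(k_grid) > 1L) {
    gain <- diff(ll) / abs(ll[-length(ll)])
    sat <- which(gain < saturation_frac)
    if (length(sat) > 0L) k_selected <- k_grid[min(sat)]
  }
  list(k_selected = k_selected, loglik_curve = curve)
}

#' Viterbi segmentation
#'
#' Computes the maximum-probability state path per chromosome and collapses
#' maximal runs of identical states into segments. Every probe belongs to
#' exactly one segment; segments never span chromosome boundaries.
#'
#' @param model An `hmm_model`.
#' @param m Probe-by-sample M-value matrix the model was trained on
#'   (same samples, rows in genomic order).
#' @param probes `probe_table` aligned with the rows of `m`.
#' @return A list of class `hmm_segments`: `table` (data frame
#'   `segment_id`, `chrom`, `start_pos`, `end_pos`, `n_probes`, `state`),
#'   `probe_state` and `probe_segment` (named integer vectors per probe).
#' @export
viterbi_segment <- function(model, m, probes) {
  stopifnot(inherits(model, "hmm_model"), is.matrix(m),
            nrow(m) == nrow(probes))
  if (ncol(m) != ncol(model$means))
    stop("sample count differs between model and matrix")
  logB <- emission_logdens(m, model$means, model$vars)
  state <- integer(nrow(m))
  for (idx in split_sequences(probes$chrom)) {
    state[idx] <- viterbi_cpp(logB[idx, , drop = FALSE], log(model$pi),
                              log(model$A))
  }
  names(state) <- probes$probe_id

  seg_key <- paste(probes$chrom, state)
  r <- rle(seg_key)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg <- data.frame(segment_id = paste0("seg_", seq_along(starts)),
                    chrom = as.character(probes$chrom[starts]),
                    start_pos = probes$pos[starts],
                    end_pos = probes$pos[ends],
                    n_probes = r$lengths,
                    state = state[starts],
                    stringsAsFactors = FALSE)
  rownames(seg) <- seg$segment_id
  probe_segment <- rep(seq_along(starts), r$lengths)
  names(probe_segment) <- probes$probe_id
  out <- list(table = seg, probe_state = state,
              probe_segment = probe_segment, k = model$k)
  class(out) <- "hmm_segments"
  out
}

#' @export
print.hmm_segments <- function(x, ...) {
  cat("hmm_segments:", nrow(x$table), "segments over",
      length(x$probe_state), "probes,", x$k, "states\n")
  invisible(x)
}

#' Per-segment median M values
#'
#' The median over a segment's member probes, per sample, used as the
#' segment's methylation proxy.
#'
#' @param segments An `hmm_segments` object.
#' @param m Probe-by-sample M (or beta) matrix aligned with the
#'   segmentation.
#' @return Segment-by-sample matrix (rownames = segment ids).
#' @export
segment_medians <- function(segments, m) {
  stopifnot(inherits(segments, "hmm_segments"),
            nrow(m) == length(segments$probe_segment))
  idx <- split(seq_len(nrow(m)), segments$probe_segment)
  out <- t(vapply(idx, function(i) col_medians(m, i), numeric(ncol(m))))
  rownames(out) <- segments$table$segment_id[as.integer(names(idx))]
  colnames(out) <- colnames(m)
  out
}

#' Per-state median M values
#'
#' The median over all probes assigned to a state (pooled across its
#' segments), per sample. States with no assigned probes are omitted with
#' a warning; downstream state selection excludes them.
#'
#' @inheritParams segment_medians
#' @return State-by-sample matrix; rownames are state indices as
#'   character. Attribute `k` records the model's state count.
#' @export
state_medians <- function(segments, m) {
  stopifnot(inherits(segments, "hmm_segments"),
            nrow(m) == length(segments$probe_state))
  idx <- split(seq_len(nrow(m)), segments$probe_state)
  empty <- setdiff(as.character(seq_len(segments$k)), names(idx))
  if (length(empty) > 0L)
    warning("state(s) with no assigned probes omitted: ",
            paste(empty, collapse = ", "))
  out <- t(vapply(idx, function(i) col_medians(m, i), numeric(ncol(m))))
  colnames(out) <- colnames(m)
  attr(out, "k") <- segments$k
  out
}

#' Serialize an HMM model to JSON
#'
#' @param model An `hmm_model`.
#' @param path Output file path.
#' @export
write_hmm_model <- function(model, path) {
  jsonlite::write_json(
    list(k = model$k, pi = model$pi, A = model$A, means = model$means,
         vars = model$vars, loglik = model$loglik, seed = model$seed,
         sample_ids = model$sample_ids),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
}
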