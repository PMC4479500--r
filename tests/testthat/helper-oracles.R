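# Independent brute-force oracles used across the suite. These never call
# the package's own recursions: likelihoods are computed by explicit path
# enumeration, p-values by labeling/table enumeration, interval operations
# by per-position flags.

# Diagonal-Gaussian emission log-densities via dnorm (independent of the
# package's matrix-algebra formulation). m: T x S; means/vars: k x S.
oracle_logB <- function(m, means, vars) {
  k <- nrow(means)
  out <- matrix(0, nrow(m), k)
  for (t in seq_len(nrow(m)))
    for (j in seq_len(k))
      out[t, j] <- sum(stats::dnorm(m[t, ], means[j, ], sqrt(vars[j, ]),
                                    log = TRUE))
  out
}

enum_paths <- function(T, k) {
  as.matrix(expand.grid(rep(list(seq_len(k)), T)))
}

oracle_path_logprob <- function(path, logB, pi, A) {
  lp <- log(pi[path[1L]]) + logB[1L, path[1L]]
  if (length(path) > 1L)
    for (t in 2:length(path))
      lp <- lp + log(A[path[t - 1L], path[t]]) + logB[t, path[t]]
  lp
}

oracle_forward_loglik <- function(logB, pi, A) {
  paths <- enum_paths(nrow(logB), length(pi))
  lp <- apply(paths, 1L, oracle_path_logprob, logB = logB, pi = pi, A = A)
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

oracle_viterbi <- function(logB, pi, A) {
  paths <- enum_paths(nrow(logB), length(pi))
  lp <- apply(paths, 1L, oracle_path_logprob, logB = logB, pi = pi, A = A)
  unname(paths[which.max(lp), ])
}

random_hmm_params <- function(k, s) {
  pi <- stats::runif(k) + 0.1
  pi <- pi / sum(pi)
  A <- matrix(stats::runif(k * k) + 0.1, k, k)
  A <- A / rowSums(A)
  means <- matrix(stats::rnorm(k * s, sd = 2), k, s)
  vars <- matrix(stats::runif(k * s, 0.2, 1.5), k, s)
  list(pi = pi, A = A, means = means, vars = vars)
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings:
# doubling of the smaller tail of the exact U distribution, capped at 1.
oracle_mwu_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  u_stat <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  obs <- u_stat(seq_len(n1))
  sel_all <- utils::combn(length(pooled), n1)
  u_all <- apply(sel_all, 2L, u_stat)
  u_min <- min(obs, n1 * length(y) - obs)
  min(1, 2 * mean(u_all <= u_min))
}

# Benjamini-Hochberg step-up recomputed from the defining formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum of the
# probabilities of all tables (same margins) with point probability at
# most that observed (with the conventional 1 + 1e-7 slack).
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_
  n <- b + d
  kk <- a + b
  supp <- max(0, kk - n):min(kk, m)
  dens <- stats::dhyper(supp, m, n, kk)
  d_obs <- stats::dhyper(a, m, n, kk)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

# Interval union per (chrom, allele) by per-position coverage flags
# (book-ended intervals merge). Coordinates must be small.
oracle_merge_intervals <- function(df) {
  out <- list()
  for (key in unique(paste(df$chrom, df$allele))) {
    sub <- df[paste(df$chrom, df$allele) == key, , drop = FALSE]
    covered <- sort(unique(unlist(Map(seq.int, sub$start, sub$end))))
    brk <- c(0L, which(diff(covered) > 1L), length(covered))
    for (i in seq_len(length(brk) - 1L)) {
      run <- covered[(brk[i] + 1L):brk[i + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = sub$chrom[1L], start = min(run), end = max(run),
        allele = sub$allele[1L], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$allele, res$start), , drop = FALSE]
}

# DMP chaining recomputed directly from the rule's definition.
oracle_chain_dmrs <- function(pos, min_probes, max_gap) {
  pos <- sort(pos)
  out <- list()
  cur <- pos[1L]
  for (p in pos[-1L]) {
    if (p - cur[length(cur)] <= max_gap) cur <- c(cur, p)
    else {
      if (length(cur) >= min_probes) out[[length(out) + 1L]] <- cur
      cur <- p
    }
  }
  if (length(cur) >= min_probes) out[[length(out) + 1L]] <- cur
  out
}
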