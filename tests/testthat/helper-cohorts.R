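# Shared fixture builders (all generated in code, seeded).

# Desk-scale cohort with one planted 8-probe block between the two
# bimodal groups; used by unit tests that need a realistic end-to-end
# input without full-cohort cost.
small_spec <- function(seed = 1L, planted = TRUE, n = 600L) {
  synthetic_spec(
    n_probes = c(`1` = n, `2` = n),
    planted_dmrs = if (planted) data.frame(
      block = "b1", group_a = "ECL", group_b = "MNSL",
      direction = "hyperA", chrom = "1", n_probes = 8L,
      spacing_bp = 200L, delta_m = 3, stringsAsFactors = FALSE) else NULL,
    n_icrs = 2L, seed = seed)
}

# Minimal probe table at given positions on one chromosome.
toy_probes <- function(pos, chrom = "1", strand = "+") {
  probe_table(data.frame(
    probe_id = sprintf("p%03d", seq_along(pos)),
    chrom = chrom, pos = as.integer(pos), strand = strand,
    stringsAsFactors = FALSE))
}

# A dmp_set built directly from probe ids (for DMR-calling tests).
toy_dmp_set <- function(hyper_a, hyper_b = character(),
                        universe = union(hyper_a, hyper_b)) {
  structure(list(comparison = c("A", "B"), hyper_a = hyper_a,
                 hyper_b = hyper_b,
                 provenance = data.frame(), universe = universe),
            class = "dmp_set")
}

# Simulate observations from a known HMM (independent of the package's
# fitting code) for parameter-recovery checks.
simulate_hmm_data <- function(n, means, vars, self_prob = 0.95,
                              seed = 1L) {
  set.seed(seed)
  k <- nrow(means)
  s <- ncol(means)
  states <- integer(n)
  states[1L] <- sample.int(k, 1L)
  for (t in 2:n)
    states[t] <- if (stats::runif(1) < self_prob) states[t - 1L] else
      sample(setdiff(seq_len(k), states[t - 1L]), 1L)
  m <- matrix(stats::rnorm(n * s, means[states, ], sqrt(vars[states, ])),
              n, s)
  rownames(m) <- sprintf("p%05d", seq_len(n))
  list(m = m, states = states)
}
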