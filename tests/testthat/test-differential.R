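# Mann-Whitney/BH testing, bootstrap stability, LASSO state selection,
# and the three-route DMP intersection.

test_that("Mann-Whitney p-values match enumeration, wilcox.test and anchors", {
  # fully tied feature: no evidence, p = 1
  m1 <- matrix(rep(1, 6), 1, dimnames = list("f1", NULL))
  r <- mwu_bh(m1, rep(c("A", "B"), each = 3))
  expect_equal(r$p_raw, 1)
  expect_false(r$significant)

  # the U = 0 anchor: {1,2,3} vs {4,5,6} gives exact two-sided p = 0.1
  m2 <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("f1", NULL))
  expect_equal(mwu_bh(m2, rep(c("A", "B"), each = 3))$p_raw, 0.1)

  # random features against full labeling enumeration and wilcox.test
  set.seed(20)
  for (i in 1:12) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, mean = runif(1, -1, 1))
    m <- matrix(c(x, y), 1, dimnames = list("f", NULL))
    lab <- rep(c("A", "B"), c(n1, n2))
    p_pkg <- mwu_bh(m, lab)$p_raw
    expect_equal(p_pkg, oracle_mwu_p(x, y), tolerance = 1e-12)
    expect_equal(p_pkg, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # tied / large-sample path agrees with the corrected normal approximation
  set.seed(21)
  for (i in 1:6) {
    x <- sample(1:5, 15, replace = TRUE)
    y <- sample(2:6, 18, replace = TRUE)
    m <- matrix(c(x, y), 1, dimnames = list("f", NULL))
    lab <- rep(c("A", "B"), c(15, 18))
    expect_equal(mwu_bh(m, lab)$p_raw,
                 suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up formula", {
  p <- c(0.005, 0.01, 0.03, 0.04)
  expect_equal(oracle_bh(p), c(0.02, 0.02, 0.04, 0.04))
  set.seed(22)
  for (i in 1:5) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # mwu_bh adjusts across all tested features
  m <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(sprintf("f%02d", 1:20),
                                                    NULL))
  res <- mwu_bh(m, rep(c("A", "B"), each = 4))
  expect_equal(res$p_adj, oracle_bh(res$p_raw))
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("bootstrap support is 1 under complete separation and low under the null", {
  set.seed(23)
  n <- 10L
  lab <- rep(c("A", "B"), each = n)
  sep <- matrix(c(rnorm(n, -2, 0.1), rnorm(n, 2, 0.1)), 1,
                dimnames = list("sep", NULL))
  expect_equal(unname(bootstrap_validate(sep, lab, seed = 9)), 1)

  null_m <- matrix(rnorm(5 * 2 * n), 5, 2 * n,
                   dimnames = list(sprintf("n%d", 1:5), NULL))
  supp <- bootstrap_validate(null_m, lab, seed = 9)
  expect_true(all(supp <= 0.3))

  # determinism: the same seed reproduces the same support exactly
  expect_identical(bootstrap_validate(null_m, lab, seed = 4),
                   bootstrap_validate(null_m, lab, seed = 4))
  expect_error(bootstrap_validate(sep, rep(c("A", "B"), c(1, 19)),
                                  seed = 1), "2 samples")
})

test_that("the delta-median-M cutoff is strict and direction follows its sign", {
  set.seed(24)
  n <- 8L
  lab <- factor(rep(c("A", "B"), each = n), levels = c("A", "B"))
  jitter <- rnorm(2 * n, sd = 1e-3)
  m <- rbind(
    at_0.89 = c(rep(0.445, n), rep(-0.445, n)) + jitter,
    at_1.50 = c(rep(0.75, n), rep(-0.75, n)) + jitter,
    down    = c(rep(-0.75, n), rep(0.75, n)) + jitter)
  res <- methylseg:::test_features(m, lab, sigma_min = 0.1, dm_min = 0.9,
                                   seed = 1)
  expect_false(res["at_0.89", "passes"])   # 0.89 <= 0.9 excludes
  expect_true(res["at_1.50", "passes"])
  expect_equal(res["at_1.50", "direction"], "hyperA")
  expect_equal(res["down", "direction"], "hyperB")
  expect_equal(res["at_0.89", "delta_median_m"], 0.89, tolerance = 0.01)

  # raising dm_min never adds passing features
  res_hi <- methylseg:::test_features(m, lab, sigma_min = 0.1,
                                      dm_min = 1.6, seed = 1)
  expect_true(all(res_hi$passes <= res$passes))
})

test_that("LASSO selects a perfectly separating state and nothing under permuted labels", {
  set.seed(25)
  n <- 40L
  lab <- rep(c("A", "B"), each = n / 2)
  state_m <- matrix(rnorm(20 * n), 20, n,
                    dimnames = list(sprintf("s%02d", 1:20), NULL))
  state_m["s07", ] <- c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3))
  sel <- lasso_state_selection(state_m, lab, seed = 3)
  expect_true("s07" %in% sel$selected)

  # permuted labels: the 1-SE rule should retain (almost) nothing
  n_sel <- vapply(1:5, function(i) {
    set.seed(200 + i)
    # extreme path tails may not converge on permuted labels; harmless
    suppressWarnings(
      length(lasso_state_selection(state_m, sample(lab),
                                   seed = 300 + i)$selected))
  }, integer(1))
  expect_lte(mean(n_sel), 1)
  expect_error(lasso_state_selection(state_m, rep("A", n)), "two group")
  expect_error(lasso_state_selection(state_m[1, , drop = FALSE], lab),
               "2 states")
})

test_that("DMP intersection is contained in every route and anti-symmetric under label swap", {
  co <- generate_cohort(small_spec(seed = 26))
  flt <- filter_probes(co$mat, crosshyb = co$crosshyb, snps = co$snps)
  fmat <- flt$matrix
  fit <- fit_hmm(fmat$m, fmat$probes$chrom, k = 4L, seed = 2,
                 n_restarts = 2L)
  seg <- viterbi_segment(fit, fmat$m, fmat$probes)
  pair <- fmat$samples$group %in% c("ECL", "MNSL")
  pm <- fmat$m[, fmat$samples$sample_id[pair]]
  run_side <- function(first, second) {
    lab <- factor(fmat$samples$group[pair], levels = c(first, second))
    routes <- route_probe_and_segment(pm, seg, lab, n_boot = 50L,
                                      seed = 5, m_filter = fmat$m)
    sm <- suppressWarnings(state_medians(seg, pm))
    sel <- lasso_state_selection(sm, lab, seed = 7)
    list(routes = routes, sel = sel,
         dmps = intersect_dmps(routes, sel, seg,
                               comparison = c(first, second)))
  }
  fwd <- run_side("ECL", "MNSL")
  planted <- unlist(co$truth$planted$probe_ids)
  expect_true(all(planted %in% fwd$dmps$hyper_a))

  # containment in each route
  probe_pass <- fwd$routes$probe$feature_id[fwd$routes$probe$passes]
  expect_true(all(fwd$dmps$hyper_a %in% probe_pass))
  expect_true(all(fwd$dmps$hyper_a %in% fwd$routes$segment_probes$probe_id))
  sel_states <- as.integer(fwd$sel$selected)
  expect_true(all(seg$probe_state[fwd$dmps$hyper_a] %in% sel_states))

  # swapping the comparison swaps the two DMP sets exactly
  rev <- run_side("MNSL", "ECL")
  expect_setequal(rev$dmps$hyper_b, fwd$dmps$hyper_a)
  expect_setequal(rev$dmps$hyper_a, fwd$dmps$hyper_b)
})

test_that("disjoint or nested route sets intersect as sets should", {
  # direct set logic on a fabricated segmentation: one passing segment
  co <- generate_cohort(small_spec(seed = 27, n = 200L))
  m <- co$mat$m
  fit <- fit_hmm(m, co$mat$probes$chrom, k = 2L, seed = 1,
                 n_restarts = 1L, max_iter = 30L)
  seg <- viterbi_segment(fit, m, co$mat$probes)
  lab <- factor(co$mat$samples$group[co$mat$samples$group %in%
                                       c("ECL", "MNSL")],
                levels = c("ECL", "MNSL"))
  pm <- m[, co$mat$samples$group %in% c("ECL", "MNSL")]
  routes <- route_probe_and_segment(pm, seg, lab, n_boot = 30L, seed = 2,
                                    m_filter = m)
  # empty state selection forces an empty intersection
  none <- list(selected = character(), coefficients = numeric())
  dmps0 <- intersect_dmps(routes, none, seg, comparison = c("ECL", "MNSL"))
  expect_length(dmps0$hyper_a, 0L)
  expect_length(dmps0$hyper_b, 0L)
  # with every state selected, the intersection equals probe & segment route
  all_states <- list(selected = as.character(seq_len(seg$k)))
  dmps1 <- intersect_dmps(routes, all_states, seg,
                          comparison = c("ECL", "MNSL"))
  probe_pass_a <- routes$probe$feature_id[routes$probe$passes &
                                            routes$probe$direction == "hyperA"]
  seg_pass_a <- routes$segment_probes$probe_id[
    routes$segment_probes$direction == "hyperA"]
  expect_setequal(dmps1$hyper_a, intersect(probe_pass_a, seg_pass_a))
})
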