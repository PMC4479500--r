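# Enrichment, imprinting/X summaries, PCA and distribution descriptors.

test_that("Fisher enrichment builds correct tables and flags no association at OR 1", {
  universe <- sprintf("p%03d", 1:200)
  cat_in <- universe[1:20]      # 10 of the DMPs, 10 of the non-DMPs...
  dmp <- universe[c(1:10, 101:190)]  # 100 DMPs, 10 inside the category
  cats <- list(balanced = c(universe[1:10], universe[191:200]))
  # table (10, 90 / 10, 90)
  res <- fisher_enrichment(dmp, universe, cats, alpha_bonf = 0.05)
  expect_equal(res$n_dmp_in, 10L)
  expect_equal(res$n_dmp_out, 90L)
  expect_equal(res$n_non_in, 10L)
  expect_equal(res$n_non_out, 90L)
  expect_equal(res$p_value, 1)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)
  expect_false(res$significant)
  expect_equal(res$log2_ratio, 0)
  # counts always reconstruct the universe
  expect_equal(res$n_dmp_in + res$n_dmp_out + res$n_non_in + res$n_non_out,
               length(universe))
  expect_error(fisher_enrichment(c(dmp, "zzz"), universe, cats), "subset")
})

test_that("Fisher p-values agree with hypergeometric enumeration on small tables", {
  # anchored toy table (8, 2 / 2, 8)
  expect_equal(fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value,
               oracle_fisher_p(8, 2, 2, 8), tolerance = 1e-9)
  set.seed(40)
  for (i in 1:15) {
    n <- sample(8:50, 1)
    a <- sample.int(n, 1)
    universe <- sprintf("u%03d", seq_len(n))
    dmp <- sample(universe, sample.int(n - 1, 1))
    cat_ids <- sample(universe, sample.int(n - 1, 1))
    res <- fisher_enrichment(dmp, universe, list(x = cat_ids),
                             alpha_bonf = 0.05)
    p_oracle <- oracle_fisher_p(res$n_dmp_in, res$n_dmp_out,
                                res$n_non_in, res$n_non_out)
    expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  }
})

test_that("enrichment handles empty categories, zero numerators and role swaps", {
  universe <- sprintf("p%03d", 1:100)
  dmp <- universe[1:20]
  cats <- list(empty = character(),
               only_non = universe[90:100],
               enriched = universe[1:15])
  expect_warning(res <- fisher_enrichment(dmp, universe, cats), "empty")
  # zero DMPs inside: log2 ratio unplottable but significance retained
  row <- res[res$category == "only_non", ]
  expect_true(is.na(row$log2_ratio))
  expect_false(is.na(row$significant))
  # swapping the DMP and non-DMP roles inverts the odds ratio
  res_fwd <- fisher_enrichment(dmp, universe, cats["enriched"])
  res_rev <- fisher_enrichment(setdiff(universe, dmp), universe,
                               cats["enriched"])
  expect_equal(res_fwd$odds_ratio, 1 / res_rev$odds_ratio,
               tolerance = 1e-6)
})

test_that("imprinting summary bands distinguish somatic, erased and uniparental ICRs", {
  spec <- synthetic_spec(
    groups = data.frame(
      name = c("SOM", "ERA", "UNI"), n_samples = 8L, sex = "M",
      profile = "bimodal",
      icr_p_state = c("somatic", "erased", "uniparental"),
      icr_m_state = c("somatic", "erased", "uniparental"),
      stringsAsFactors = FALSE),
    n_probes = c(`1` = 400L, `2` = 400L), planted_dmrs = NULL,
    n_icrs = 4L, seed = 50)
  co <- generate_cohort(spec)
  cats <- classify_probes(co$mat$probes, co$imprint)
  s <- imprinting_summary(co$mat, cats[c("ICR_P", "ICR_M")])
  get <- function(g, cat, col) s[s$group == g & s$category == cat, col]
  expect_equal(get("SOM", "ICR_P", "band"), "somatic")
  expect_equal(get("SOM", "ICR_P", "median"), 0.5, tolerance = 0.1)
  expect_equal(get("ERA", "ICR_M", "band"), "erased")
  expect_equal(get("UNI", "ICR_P", "band"), "uniparental")
  expect_gt(get("UNI", "ICR_M", "median"), 0.9)
  expect_error(imprinting_summary(co$mat, cats["ICR_P"], groups = "NOPE"),
               "empty group")
})

test_that("female X is hemi-methylated while male X stays bimodal", {
  spec <- synthetic_spec(
    groups = data.frame(
      name = c("FEM", "MAL"), n_samples = 8L, sex = c("F", "M"),
      profile = "bimodal", icr_p_state = "somatic",
      icr_m_state = "somatic", stringsAsFactors = FALSE),
    n_probes = c(`1` = 300L, X = 300L), planted_dmrs = NULL,
    n_icrs = 0L, seed = 51)
  co <- generate_cohort(spec)
  cats <- classify_probes(co$mat$probes, co$imprint)
  s <- imprinting_summary(co$mat, cats["X_CHROM"])
  fem <- s[s$group == "FEM", ]
  mal <- s[s$group == "MAL", ]
  expect_equal(fem$median, 0.5, tolerance = 0.05)
  expect_gt(fem$q25, 0.3)       # concentrated around hemi-methylation
  expect_lt(fem$q75, 0.7)
  expect_lt(mal$q25, 0.25)      # bimodal spread toward the extremes
  expect_gt(mal$q75, 0.75)
})

test_that("PCA separates distinct global profiles and bootstraps deterministically", {
  # near-disjoint constant profiles: silhouette close to 1
  set.seed(52)
  m <- cbind(matrix(rnorm(50 * 5, -2, 0.05), 50, 5),
             matrix(rnorm(50 * 5, 2, 0.05), 50, 5))
  colnames(m) <- sprintf("s%02d", 1:10)
  res <- pca_summary(m, rep(c("A", "B"), each = 5), n_boot = 20L, seed = 1)
  expect_gt(res$silhouette, 0.95)
  # single group: silhouette undefined
  res1 <- pca_summary(m, rep("A", 10), n_boot = 5L, seed = 1)
  expect_true(is.na(res1$silhouette))
  # determinism
  res2 <- pca_summary(m, rep(c("A", "B"), each = 5), n_boot = 20L,
                      seed = 1)
  expect_identical(res$boot_silhouette, res2$boot_silhouette)

  # three groups with distinct methylation profiles separate well
  spec <- synthetic_spec(
    groups = data.frame(
      name = c("ECL", "SEL", "SSL"), n_samples = 10L, sex = "M",
      profile = c("bimodal", "intermediate", "hypomethylated"),
      icr_p_state = "somatic", icr_m_state = "somatic",
      stringsAsFactors = FALSE),
    n_probes = c(`1` = 800L), planted_dmrs = NULL, n_icrs = 0L,
    seed = 53)
  co <- generate_cohort(spec)
  pr <- pca_summary(co$mat$m, co$mat$samples$group, n_boot = 30L,
                    seed = 2)
  expect_gt(pr$mean_boot_silhouette, 0.5)
  expect_error(pca_summary(m[, 1:2], c("A", "B")), "3 samples")
})

test_that("beta distribution summaries integrate to one and show the expected modes", {
  co <- generate_cohort(small_spec(seed = 54, planted = FALSE))
  ds <- distribution_summary(co$mat, groups = c("ECL", "SSL"))
  for (g in names(ds)) {
    d <- ds[[g]]$density
    area <- sum((d$y[-1] + d$y[-nrow(d)]) / 2 * diff(d$x))
    expect_equal(area, 1, tolerance = 1e-6)
  }
  # bimodal group: local maxima near 0.1 and 0.9
  d <- ds$ECL$density
  peaks <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  expect_true(any(peaks > 0.02 & peaks < 0.25))
  expect_true(any(peaks > 0.75 & peaks < 0.98))
  # hypomethylated group piles up low
  expect_lt(ds$SSL$quantiles[["q75"]], 0.3)

  # constant input: all quantiles equal the constant
  co2 <- co
  co2$mat$beta[1:5, ] <- 0.3
  dc <- distribution_summary(co2$mat,
                             subset_ids = co2$mat$probes$probe_id[1:5],
                             groups = "ECL", bw = 0.05)
  expect_true(all(dc$ECL$quantiles == 0.3))
})
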