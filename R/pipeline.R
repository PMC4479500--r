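# End-to-end comparison workflow: probe filtering, annotation, HMM
# segmentation, three-route DMP selection, DMR calling, enrichment and
# imprinting summaries, with a machine-readable run manifest.

#' Configure a pairwise comparison
#'
#' Collects the group pair and every protocol threshold. Merged groups
#' are supported by passing several labels for one side (e.g.
#' `group_a = c("SE", "DG")`).
#'
#' @param group_a,group_b Group label(s) of each side; `group_a` is the
#'   reference for the `hyperA` direction.
#' @param alpha Significance level on BH-adjusted p-values.
#' @param dm_min Minimal absolute difference of group median M values.
#' @param sigma_probe,sigma_segment Low-variability thresholds.
#' @param n_boot,support_min Bootstrap replicates and required support.
#' @param k Number of HMM states.
#' @param n_restarts HMM training restarts.
#' @param min_probes,max_gap_bp DMR calling rule.
#' @param flank_frac DMR annotation flank fraction.
#' @param detect_p_thresh,detect_frac Detection filter parameters.
#' @param seed Integer seed governing HMM training, bootstrap and LASSO
#'   folds.
#' @return A list of class `comparison_config`.
#' @export
comparison_config <- function(group_a, group_b, alpha = 0.05,
                              dm_min = 0.9, sigma_probe = 0.8,
                              sigma_segment = 0.6, n_boot = 100L,
                              support_min = 0.95, k = 20L,
                              n_restarts = 3L, min_probes = 5L,
                              max_gap_bp = 1000L, flank_frac = 0.2,
                              detect_p_thresh = 0.01, detect_frac = 0.95,
                              seed = 1L) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L,
            alpha > 0, dm_min > 0, sigma_probe > 0, sigma_segment > 0,
            n_boot > 0, support_min > 0, k >= 1L, min_probes >= 1L,
            max_gap_bp > 0, flank_frac >= 0)
  if (length(intersect(group_a, group_b)) > 0L)
    stop("group_a and group_b must be disjoint")
  out <- as.list(environment())
  class(out) <- "comparison_config"
  out
}

#' Run the full pairwise comparison workflow
#'
#' Stage order: probe filtering, functional annotation, HMM segmentation
#' (trained on all tumor samples, cell lines excluded), probe- and
#' segment-route testing plus LASSO state selection on the compared pair,
#' DMP intersection, DMR calling and annotation, Fisher enrichment
#' (functional + per-chromosome + per-state categories, Bonferroni
#' threshold over the whole family) and imprinting/X summaries. The
#' result is a pure function of (inputs, config): rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A `comparison_config`.
#' @param inputs A `synthetic_cohort` or a list with elements `probes`
#'   (`probe_table`), `mat` (`methylation_matrix`), `imprint`
#'   (`imprint_resource`), and optionally `genes`, `crosshyb`, `snps`.
#' @param out_dir Optional directory; when given, DMP/DMR tables, the
#'   enrichment table, the model and the run manifest are written there.
#' @param verbose Emit per-stage progress messages.
#' @return A list of class `comparison_result`: `config`,
#'   `filter_report`, `model`, `segments`, `routes`, `state_selection`,
#'   `dmps`, `dmrs`, `enrichment`, `imprinting`, `categories`,
#'   `manifest`.
#' @export
run_comparison <- function(config, inputs, out_dir = NULL,
                           verbose = TRUE) {
  stopifnot(inherits(config, "comparison_config"))
  say <- function(...) if (verbose) message("[", format(Sys.time(),
                                                        "%H:%M:%S"),
                                            "] ", ...)
  groups_avail <- unique(inputs$mat$samples$group)
  missing_groups <- setdiff(c(config$group_a, config$group_b),
                            groups_avail)
  if (length(missing_groups) > 0L)
    stop("stage groups: label(s) not in sample metadata: ",
         paste(missing_groups, collapse = ", "))

  say("stage filter: ", nrow(inputs$mat$beta), " probes")
  flt <- filter_probes(inputs$mat,
                       crosshyb = inputs$crosshyb %||% character(),
                       snps = inputs$snps,
                       detect_p_thresh = config$detect_p_thresh,
                       detect_frac = config$detect_frac)
  fmat <- flt$matrix

  say("stage annotate")
  categories <- classify_probes(fmat$probes, inputs$imprint)

  tumor_ids <- fmat$samples$sample_id[!fmat$samples$is_cell_line]
  tmat <- subset_samples(fmat, tumor_ids)
  say("stage segment: k = ", config$k, " on ", length(tumor_ids),
      " tumor samples")
  model <- fit_hmm(tmat$m, tmat$probes$chrom, k = config$k,
                   seed = config$seed, n_restarts = config$n_restarts)
  segments <- viterbi_segment(model, tmat$m, tmat$probes)
  say("  ", nrow(segments$table), " segments")

  label_a <- paste(config$group_a, collapse = "+")
  label_b <- paste(config$group_b, collapse = "+")
  in_pair <- tmat$samples$group %in% c(config$group_a, config$group_b)
  pair_ids <- tmat$samples$sample_id[in_pair]
  pmat <- subset_samples(tmat, pair_ids)
  labels <- factor(ifelse(pmat$samples$group %in% config$group_a,
                          label_a, label_b),
                   levels = c(label_a, label_b))

  say("stage routes: ", label_a, " (", sum(labels == label_a),
      ") vs ", label_b, " (", sum(labels == label_b), ")")
  routes <- route_probe_and_segment(
    pmat$m, segments, labels,
    sigma_probe = config$sigma_probe,
    sigma_segment = config$sigma_segment,
    dm_min = config$dm_min, alpha = config$alpha,
    n_boot = config$n_boot, support_min = config$support_min,
    seed = config$seed, m_filter = tmat$m)

  say("stage states: LASSO over ", segments$k, " states")
  state_m <- suppressWarnings(state_medians(segments, pmat$m))
  state_sel <- lasso_state_selection(state_m, labels,
                                     seed = config$seed + 2L)
  say("  selected state(s): ",
      if (length(state_sel$selected) == 0L) "none" else
        paste(state_sel$selected, collapse = ", "))

  dmps <- intersect_dmps(routes, state_sel, segments,
                         comparison = c(label_a, label_b),
                         dm_min = config$dm_min)
  say("stage intersect: ", length(dmps$hyper_a), " hyper-", label_a,
      ", ", length(dmps$hyper_b), " hyper-", label_b)

  dmrs <- call_dmrs(dmps, fmat$probes, min_probes = config$min_probes,
                    max_gap_bp = config$max_gap_bp)
  if (!is.null(inputs$genes))
    dmrs <- annotate_dmrs(dmrs, inputs$genes,
                          flank_frac = config$flank_frac)
  say("stage dmr: ", nrow(dmrs), " regions")

  n_dmp <- length(dmps$hyper_a) + length(dmps$hyper_b)
  enrichment <- NULL
  if (n_dmp == 0L) {
    say("stage enrich: no DMPs; enrichment skipped")
  } else {
    chrom_cats <- chromosome_categories(
      fmat$probes, chroms = intersect(CHROM_LEVELS,
                                      unique(fmat$probes$chrom)))
    state_cats <- state_categories(segments)
    all_cats <- c(unclass(categories), chrom_cats, state_cats)
    # the Bonferroni family counts every constructed category, including
    # those empty on this probe universe (which are not testable)
    alpha_bonf <- config$alpha /
      (length(categories) + length(chrom_cats) + length(state_cats))
    all_cats <- all_cats[vapply(all_cats, length, integer(1)) > 0L]
    enrichment <- list(
      hyper_a = fisher_enrichment(dmps$hyper_a, fmat$probes$probe_id,
                                  all_cats, alpha_bonf = alpha_bonf),
      hyper_b = if (length(dmps$hyper_b) > 0L)
        fisher_enrichment(dmps$hyper_b, fmat$probes$probe_id,
                          all_cats, alpha_bonf = alpha_bonf) else NULL)
    say("stage enrich: alpha_bonf = ", format(alpha_bonf))
  }

  imprint_cats <- categories[c("ICR_P", "ICR_M", "X_CHROM")]
  imprint_cats <- imprint_cats[vapply(imprint_cats, length,
                                      integer(1)) > 0L]
  imprinting <- if (length(imprint_cats) > 0L)
    imprinting_summary(tmat, imprint_cats) else NULL

  manifest <- list(
    package = "methylseg",
    version = as.character(utils::packageVersion("methylseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    comparison = c(label_a, label_b),
    thresholds = config[c("alpha", "dm_min", "sigma_probe",
                          "sigma_segment", "n_boot", "support_min", "k",
                          "n_restarts", "min_probes", "max_gap_bp",
                          "flank_frac", "detect_p_thresh",
                          "detect_frac")],
    seed = config$seed,
    counts = list(n_input = flt$report$n_input,
                  n_valid = flt$report$n_valid,
                  n_segments = nrow(segments$table),
                  n_dmp_hyper_a = length(dmps$hyper_a),
                  n_dmp_hyper_b = length(dmps$hyper_b),
                  n_dmr = nrow(dmrs)))

  result <- list(config = config, filter_report = flt$report,
                 model = model, segments = segments, routes = routes,
                 state_selection = state_sel, dmps = dmps, dmrs = dmrs,
                 enrichment = enrichment, imprinting = imprinting,
                 categories = categories, manifest = manifest)
  class(result) <- "comparison_result"

  if (!is.null(out_dir)) write_comparison(result, out_dir)
  result
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("comparison_result:", paste(x$manifest$comparison,
                                  collapse = " vs "), "\n")
  cat("  valid probes:", x$manifest$counts$n_valid,
      " segments:", x$manifest$counts$n_segments, "\n")
  cat("  DMPs:", x$manifest$counts$n_dmp_hyper_a, "/",
      x$manifest$counts$n_dmp_hyper_b, "(hyperA/hyperB)",
      " DMRs:", x$manifest$counts$n_dmr, "\n")
  invisible(x)
}

#' Write comparison artifacts
#'
#' Writes DMP and DMR tables (TSV + BED), the enrichment tables, the HMM
#' model (JSON) and the run manifest (JSON) to a directory.
#'
#' @param result A `comparison_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_comparison <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$dmps$provenance,
                     file.path(out_dir, "dmps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dmr_flat <- result$dmrs
  dmr_flat$probe_ids <- vapply(dmr_flat$probe_ids, paste,
                               character(1), collapse = ";")
  utils::write.table(dmr_flat, file.path(out_dir, "dmrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dmr_bed(result$dmrs, file.path(out_dir, "dmrs.bed"))
  if (!is.null(result$enrichment)) {
    utils::write.table(result$enrichment$hyper_a,
                       file.path(out_dir, "enrichment_hyper_a.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$enrichment$hyper_b))
      utils::write.table(result$enrichment$hyper_b,
                         file.path(out_dir, "enrichment_hyper_b.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$imprinting))
    utils::write.table(result$imprinting,
                       file.path(out_dir, "imprinting.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_hmm_model(result$model, file.path(out_dir, "hmm_model.json"))
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
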