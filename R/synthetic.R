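# Seeded synthetic cohort generator with planted ground truth.
#
# Emulates the statistical structure the pipeline assumes: per-group beta
# distributions drawn from two-component Beta mixtures (bimodal profiles
# with modes near 0.1/0.9, globally hypomethylated profiles, intermediate
# profiles with an upper mode near 0.55), spatially persistent methylation
# regimes along each chromosome, somatic/erased/uniparental ICR
# methylation per group, hemi-methylated X in female groups, and planted
# DMP/DMR blocks with known truth. All output is deterministic given the
# spec's seed.

PROFILE_MODES <- list(
  bimodal        = c(low = 0.10, high = 0.90),
  hypomethylated = c(low = 0.08, high = 0.15),
  intermediate   = c(low = 0.10, high = 0.55))

ICR_MODES <- c(somatic = 0.50, erased = 0.05, uniparental = 0.95)

default_groups <- function() {
  data.frame(
    name = c("ECL", "MNSL", "SEL", "SSL"),
    n_samples = 12L,
    sex = c("M", "M", "F", "M"),
    profile = c("bimodal", "bimodal", "intermediate", "hypomethylated"),
    icr_p_state = c("somatic", "somatic", "erased", "uniparental"),
    icr_m_state = c("somatic", "somatic", "erased", "uniparental"),
    stringsAsFactors = FALSE)
}

default_planted <- function() {
  data.frame(
    block = c("block1", "block2", "block3"),
    group_a = "ECL", group_b = "MNSL", direction = "hyperA",
    chrom = c("1", "2", "3"),
    n_probes = 8L, spacing_bp = 200L, delta_m = 3,
    stringsAsFactors = FALSE)
}

#' Specify a synthetic methylation cohort
#'
#' Collects the generating conditions for [generate_cohort()]. The
#' defaults describe the cohort used throughout the package's validation:
#' four groups of 12 samples (two sharing the bimodal profile and serving
#' as the differential comparison, one intermediate female group, one
#' globally hypomethylated group), 20,000 probes over four autosomes, and
#' three planted 8-probe DMR blocks at a median-M difference of 3 between
#' the two bimodal groups.
#'
#' @param groups Data frame (`name`, `n_samples`, `sex`, `profile`,
#'   `icr_p_state`, `icr_m_state`). Profiles: `bimodal`,
#'   `hypomethylated`, `intermediate`; ICR states: `somatic`, `erased`,
#'   `uniparental`.
#' @param n_probes Named integer vector: probes per chromosome.
#' @param median_gap,gap_sdlog Log-normal inter-probe gap distribution
#'   (bp).
#' @param mode_switch_prob Per-step probability that the baseline
#'   methylation regime (low/high) flips between adjacent probes.
#' @param beta_concentration Beta-distribution concentration around each
#'   mode (larger = tighter).
#' @param planted_dmrs Data frame (`block`, `group_a`, `group_b`,
#'   `direction`, `chrom`, `n_probes`, `spacing_bp`, `delta_m`) of
#'   planted differential blocks; the hypermethylated group is `group_a`
#'   for direction `hyperA`, `group_b` for `hyperB`.
#' @param n_icrs Number of generated ICR intervals (alternating P/M
#'   alleles on the first chromosomes).
#' @param icr_n_probes Probes covered by each ICR.
#' @param detection_fail_rate Per-entry probability of a failed detection
#'   p-value.
#' @param n_failed_probes Background probes forced to fail detection in
#'   all samples.
#' @param n_crosshyb,n_snp Sizes of the generated exclusion lists (half
#'   of the SNP records are non-excluding by design).
#' @param seed Integer seed governing all randomness.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(groups = default_groups(),
                           n_probes = c(`1` = 5000L, `2` = 5000L,
                                        `3` = 5000L, `4` = 5000L),
                           median_gap = 1500, gap_sdlog = 0.8,
                           mode_switch_prob = 0.05,
                           beta_concentration = 60,
                           planted_dmrs = default_planted(),
                           n_icrs = 6L, icr_n_probes = 8L,
                           detection_fail_rate = 0.002,
                           n_failed_probes = 3L,
                           n_crosshyb = 10L, n_snp = 10L,
                           seed = 1L) {
  if (anyDuplicated(groups$name)) stop("group names must be unique")
  stopifnot(all(groups$profile %in% names(PROFILE_MODES)),
            all(groups$icr_p_state %in% names(ICR_MODES)),
            all(groups$icr_m_state %in% names(ICR_MODES)))
  if (!is.null(planted_dmrs) && nrow(planted_dmrs) > 0L) {
    stopifnot(all(planted_dmrs$group_a %in% groups$name),
              all(planted_dmrs$group_b %in% groups$name),
              all(planted_dmrs$direction %in% c("hyperA", "hyperB")),
              all(as.character(planted_dmrs$chrom) %in% names(n_probes)))
    if (any(planted_dmrs$n_probes >
            n_probes[as.character(planted_dmrs$chrom)] - 100L))
      stop("planted DMR larger than its chromosome allows")
  }
  out <- list(groups = groups, n_probes = n_probes,
              median_gap = median_gap, gap_sdlog = gap_sdlog,
              mode_switch_prob = mode_switch_prob,
              beta_concentration = beta_concentration,
              planted_dmrs = planted_dmrs,
              n_icrs = n_icrs, icr_n_probes = icr_n_probes,
              detection_fail_rate = detection_fail_rate,
              n_failed_probes = n_failed_probes,
              n_crosshyb = n_crosshyb, n_snp = n_snp,
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

rbeta_mode <- function(n, mode, concentration) {
  a <- 1 + mode * (concentration - 2)
  b <- 1 + (1 - mode) * (concentration - 2)
  stats::rbeta(n, a, b)
}

# Sample a run start avoiding previously used index ranges.
pick_run <- function(n_chrom, len, used, margin = 50L) {
  for (i in 1:200) {
    s <- sample.int(n_chrom - 2L * margin - len, 1L) + margin
    span <- seq.int(s, s + len - 1L)
    if (!any(span %in% used)) return(span)
  }
  stop("could not place a non-overlapping probe run")
}

#' Generate a synthetic cohort
#'
#' Draws probe coordinates, annotation, group-wise beta values, detection
#' p-values, exclusion lists and imprinting resources according to a
#' [synthetic_spec()], planting the specified differential blocks by
#' shifting the affected group's M values by `delta_m` (through the logit
#' transform, so all beta values stay in `[0, 1]`).
#'
#' @param spec A `synthetic_spec`.
#' @return A list of class `synthetic_cohort`: `probes` (`probe_table`),
#'   `mat` (`methylation_matrix`), `imprint` (`imprint_resource`),
#'   `genes` (gene-model data frame), `crosshyb`, `snps`, and `truth`
#'   (planted blocks with member probes, per-group ICR/X states, forced
#'   exclusions).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  chroms <- names(spec$n_probes)

  # --- probe coordinates, baseline regime, special runs -------------------
  probe_rows <- list()
  planted <- spec$planted_dmrs
  has_planted <- !is.null(planted) && nrow(planted) > 0L
  planted_idx <- vector("list", if (has_planted) nrow(planted) else 0L)
  icr_rows <- list()
  icr_probe_idx <- list()
  offset <- 0L
  icr_count <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n <- spec$n_probes[[ch]]
    gaps <- pmax(1, round(stats::rlnorm(n - 1L, log(spec$median_gap),
                                        spec$gap_sdlog)))
    used <- integer(0)
    # planted blocks on this chromosome: contiguous runs at fixed spacing
    if (has_planted) {
      for (bi in which(as.character(planted$chrom) == ch)) {
        span <- pick_run(n, planted$n_probes[bi], used)
        used <- c(used, span)
        gaps[span[-length(span)]] <- planted$spacing_bp[bi]
        planted_idx[[bi]] <- offset + span
      }
    }
    # ICR intervals: alternate alleles over the first chromosomes
    n_icr_here <- if (spec$n_icrs > 0L)
      sum(seq_len(spec$n_icrs) %% length(chroms) + 1L == ci) else 0L
    for (r in seq_len(n_icr_here)) {
      icr_count <- icr_count + 1L
      span <- pick_run(n, spec$icr_n_probes, used)
      used <- c(used, span)
      gaps[span[-length(span)]] <- 300L
      icr_probe_idx[[icr_count]] <- offset + span
      icr_rows[[icr_count]] <- list(chrom = ch, span = span,
                                    allele = c("P", "M")[icr_count %% 2 + 1])
    }
    pos <- 10000L + cumsum(c(0L, gaps))
    # baseline low/high regime as a persistent two-state chain
    regime <- character(n)
    regime[1L] <- sample(c("low", "high"), 1L)
    flip <- stats::runif(n - 1L) < spec$mode_switch_prob
    for (t in 2:n) regime[t] <- if (flip[t - 1L])
      setdiff(c("low", "high"), regime[t - 1L]) else regime[t - 1L]
    probe_rows[[ci]] <- data.frame(chrom = ch, pos = as.integer(pos),
                                   regime = regime,
                                   stringsAsFactors = FALSE)
    offset <- offset + n
  }
  pr <- do.call(rbind, probe_rows)
  n_total <- nrow(pr)
  pr$probe_id <- sprintf("cg%08d", seq_len(n_total))
  pr$strand <- rep_len(c("+", "-"), n_total)

  is_planted <- rep(FALSE, n_total)
  for (span in planted_idx) is_planted[span] <- TRUE
  pr$regime[is_planted] <- "low"  # shared low baseline under every profile
  icr_allele <- rep(NA_character_, n_total)
  for (i in seq_along(icr_probe_idx))
    icr_allele[icr_probe_idx[[i]]] <- icr_rows[[i]]$allele

  # --- gene model & manifest annotation ----------------------------------
  genes <- list()
  gene_sym <- rep("", n_total)
  tss_class <- rep("none", n_total)
  region <- rep("", n_total)
  gi <- 0L
  row0 <- 0L
  for (ci in seq_along(chroms)) {
    n <- spec$n_probes[[chroms[ci]]]
    starts <- seq(1L, n, by = 40L)
    for (s in starts) {
      gi <- gi + 1L
      span <- row0 + seq.int(s, min(s + 39L, n))
      sym <- sprintf("GENE%s_%d", chroms[ci], gi)
      genes[[gi]] <- data.frame(chrom = chroms[ci],
                                start = pr$pos[span[1L]],
                                end = pr$pos[span[length(span)]],
                                symbol = sym, stringsAsFactors = FALSE)
      gene_sym[span] <- sym
      tss_class[span[1L]] <- "TSS200"
      if (length(span) > 1L) tss_class[span[2L]] <- "TSS1500"
      if (length(span) > 1L) region[span[2L]] <- "5'UTR"
      if (length(span) > 2L) region[span[3L]] <- "EXON1"
      if (length(span) > 4L)
        region[span[4:(length(span) - 1L)]] <- "GENE.BODY"
      region[span[length(span)]] <- "3'UTR"
    }
    row0 <- row0 + n
  }
  genes <- do.call(rbind, genes)
  manifest <- data.frame(
    probe_id = pr$probe_id, chrom = pr$chrom, pos = pr$pos,
    strand = pr$strand, gene_symbols = gene_sym,
    tss_distance_class = tss_class, region_classes = region,
    island = stats::runif(n_total) < 0.3,
    repeat_class = sample(c("none", "LINE", "SINE"), n_total,
                          replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    mir = stats::runif(n_total) < 0.005,
    snrna = stats::runif(n_total) < 0.005,
    stringsAsFactors = FALSE)
  probes <- probe_table(manifest)  # already in (chrom, pos) order

  # --- imprinting resources ----------------------------------------------
  if (length(icr_rows) > 0L) {
    icr_df <- do.call(rbind, lapply(seq_along(icr_rows), function(i) {
      idx <- icr_probe_idx[[i]]
      data.frame(chrom = icr_rows[[i]]$chrom,
                 start = pr$pos[idx[1L]] - 50L,
                 end = pr$pos[idx[length(idx)]] + 50L,
                 allele = icr_rows[[i]]$allele, stringsAsFactors = FALSE)
    }))
    tss_df <- data.frame(gene = sprintf("IMP%d", seq_len(nrow(icr_df))),
                         chrom = icr_df$chrom,
                         tss = icr_df$end + 100L, strand = "+",
                         allele = icr_df$allele, stringsAsFactors = FALSE)
  } else {
    icr_df <- data.frame(chrom = character(), start = integer(),
                         end = integer(), allele = character(),
                         stringsAsFactors = FALSE)
    tss_df <- data.frame(gene = character(), chrom = character(),
                         tss = integer(), strand = character(),
                         allele = character(), stringsAsFactors = FALSE)
  }
  imprint <- imprint_resource(tss_df, icr_df, probes = probes)

  # --- beta values --------------------------------------------------------
  grp <- spec$groups
  sample_id <- unlist(lapply(seq_len(nrow(grp)), function(g)
    sprintf("%s_%02d", grp$name[g], seq_len(grp$n_samples[g]))))
  samples <- data.frame(
    sample_id = sample_id,
    group = rep(grp$name, grp$n_samples),
    sex = rep(grp$sex, grp$n_samples),
    site = "gonad",
    is_cell_line = FALSE, stringsAsFactors = FALSE)

  beta <- matrix(NA_real_, n_total, nrow(samples),
                 dimnames = list(pr$probe_id, samples$sample_id))
  for (g in seq_len(nrow(grp))) {
    modes <- PROFILE_MODES[[grp$profile[g]]][pr$regime]
    modes[is_planted] <- PROFILE_MODES[[grp$profile[g]]][["low"]]
    icr_state <- ifelse(icr_allele == "P", grp$icr_p_state[g],
                        grp$icr_m_state[g])
    modes[!is.na(icr_allele)] <- ICR_MODES[icr_state[!is.na(icr_allele)]]
    if (grp$sex[g] == "F") modes[pr$chrom == "X"] <- 0.5
    cols <- which(samples$group == grp$name[g])
    for (s in cols)
      beta[, s] <- rbeta_mode(n_total, modes, spec$beta_concentration)
  }
  # planted M-space shifts for the affected group
  if (has_planted) {
    for (bi in seq_len(nrow(planted))) {
      target <- if (planted$direction[bi] == "hyperA")
        planted$group_a[bi] else planted$group_b[bi]
      cols <- which(samples$group == target)
      idx <- planted_idx[[bi]]
      beta[idx, cols] <-
        m_to_beta(beta_to_m(beta[idx, cols, drop = FALSE]) +
                    planted$delta_m[bi])
    }
  }

  # --- detection p-values & exclusion lists -------------------------------
  detection_p <- matrix(stats::runif(length(beta), 0, 1e-4),
                        n_total, ncol(beta), dimnames = dimnames(beta))
  fail <- stats::runif(length(beta)) < spec$detection_fail_rate
  detection_p[fail] <- stats::runif(sum(fail), 0.05, 1)
  background <- which(!is_planted & is.na(icr_allele))
  special <- sample(background,
                    spec$n_failed_probes + spec$n_crosshyb + spec$n_snp)
  failed_ids <- pr$probe_id[special[seq_len(spec$n_failed_probes)]]
  detection_p[failed_ids, ] <- stats::runif(
    spec$n_failed_probes * ncol(beta), 0.05, 1)
  crosshyb <- pr$probe_id[special[spec$n_failed_probes +
                                    seq_len(spec$n_crosshyb)]]
  snp_ids <- pr$probe_id[special[spec$n_failed_probes + spec$n_crosshyb +
                                   seq_len(spec$n_snp)]]
  n_hit <- ceiling(spec$n_snp / 2)
  snps <- data.frame(
    probe_id = snp_ids,
    distance_bp = c(rep(0L, n_hit), rep(50L, spec$n_snp - n_hit)),
    allele_freq = c(rep(0.2, n_hit), rep(0.2, spec$n_snp - n_hit)),
    stringsAsFactors = FALSE)

  mat <- methylation_matrix(beta, probes, samples,
                            detection_p = detection_p)

  truth_planted <- if (has_planted) {
    cbind(planted,
          data.frame(start_pos = vapply(planted_idx, function(i)
            pr$pos[i[1L]], integer(1)),
            end_pos = vapply(planted_idx, function(i)
              pr$pos[i[length(i)]], integer(1))),
          probe_ids = I(lapply(planted_idx, function(i) pr$probe_id[i])))
  } else NULL
  truth <- list(
    planted = truth_planted,
    icr_probes = split(pr$probe_id[!is.na(icr_allele)],
                       icr_allele[!is.na(icr_allele)]),
    group_states = grp[, c("name", "profile", "icr_p_state",
                           "icr_m_state", "sex")],
    excluded = list(failed_detection = failed_ids, crosshyb = crosshyb,
                    snp_hit = snps$probe_id[seq_len(n_hit)]))
  out <- list(probes = probes, mat = mat, imprint = imprint,
              genes = genes, crosshyb = crosshyb, snps = snps,
              truth = truth, spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

#' Generate a fully null cohort
#'
#' Same generator, but with no planted effects and every group sharing
#' one generating distribution (bimodal profile, somatic ICRs, male sex),
#' so that any downstream DMP call is a false positive. Group names and
#' sizes are preserved.
#'
#' @param spec A `synthetic_spec`; its group structure and sizes are kept.
#' @return A `synthetic_cohort` whose truth records zero planted effects.
#' @export
null_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (nrow(spec$groups) < 2L) stop("at least 2 groups required")
  spec$groups$profile <- "bimodal"
  spec$groups$icr_p_state <- "somatic"
  spec$groups$icr_m_state <- "somatic"
  spec$groups$sex <- "M"
  spec$planted_dmrs <- NULL
  generate_cohort(spec)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `manifest.tsv`, `beta.tsv`, `detection_p.tsv`, `samples.tsv`,
#' `icrs.tsv`, `imprinted_tss.tsv`, `genes.tsv`, `crosshyb.txt`,
#' `snps.tsv` and `truth.json` under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name, row.names = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = row.names,
                       col.names = TRUE)
  man <- cohort$probes
  class(man) <- "data.frame"
  w(man, "manifest.tsv")
  beta <- data.frame(probe_id = rownames(cohort$mat$beta),
                     cohort$mat$beta, check.names = FALSE)
  w(beta, "beta.tsv")
  detp <- data.frame(probe_id = rownames(cohort$mat$detection_p),
                     cohort$mat$detection_p, check.names = FALSE)
  w(detp, "detection_p.tsv")
  w(cohort$mat$samples, "samples.tsv")
  icrs <- cohort$imprint$icrs
  class(icrs) <- "data.frame"
  w(icrs[, c("chrom", "start", "end", "allele")], "icrs.tsv")
  w(cohort$imprint$imprinted_tss, "imprinted_tss.tsv")
  w(cohort$genes, "genes.tsv")
  writeLines(cohort$crosshyb, file.path(dir, "crosshyb.txt"))
  w(cohort$snps, "snps.tsv")
  truth <- cohort$truth
  if (!is.null(truth$planted)) {
    truth$planted$probe_ids <- lapply(truth$planted$probe_ids, identity)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a beta matrix and sample metadata written by [write_cohort()]
#'
#' @param dir Directory containing `beta.tsv`, `samples.tsv`,
#'   `manifest.tsv` and optionally `detection_p.tsv`.
#' @return A `methylation_matrix`.
#' @export
load_beta_matrix <- function(dir) {
  probes <- load_manifest(file.path(dir, "manifest.tsv"))
  rd <- function(name) {
    df <- utils::read.table(file.path(dir, name), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  beta <- rd("beta.tsv")
  detp_path <- file.path(dir, "detection_p.tsv")
  detection_p <- if (file.exists(detp_path)) rd("detection_p.tsv") else NULL
  samples <- utils::read.table(file.path(dir, "samples.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  methylation_matrix(beta, probes, samples, detection_p = detection_p)
}
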