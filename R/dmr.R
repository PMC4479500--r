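# DMR calling from adjacent DMPs, flanked gene annotation, recurrence.

#' Call differentially methylated regions
#'
#' Within each chromosome and direction, DMPs sorted by position are
#' chained while successive DMPs are at most `max_gap_bp` apart
#' (boundary value allowed); maximal chains with at least `min_probes`
#' members become DMRs. Intervening non-DMP array probes do not break a
#' chain: only the inter-DMP distance is constrained.
#'
#' @param dmps A `dmp_set`.
#' @param probes `probe_table` providing DMP coordinates.
#' @param min_probes Minimal DMP count per region (default 5).
#' @param max_gap_bp Maximal distance between successive DMPs (default
#'   1000).
#' @return Data frame of class `dm_records`: `comparison`, `direction`,
#'   `chrom`, `start_pos`, `end_pos`, `n_dmps`, `probe_ids` (list
#'   column). Empty input yields an empty frame.
#' @export
call_dmrs <- function(dmps, probes, min_probes = 5L, max_gap_bp = 1000L) {
  stopifnot(inherits(dmps, "dmp_set"), inherits(probes, "probe_table"))
  comparison <- paste(dmps$comparison, collapse = "_vs_")
  recs <- list()
  for (dir in c("hyperA", "hyperB")) {
    ids <- if (dir == "hyperA") dmps$hyper_a else dmps$hyper_b
    if (length(ids) == 0L) next
    df <- probes[probes$probe_id %in% ids, c("probe_id", "chrom", "pos")]
    df <- df[order(chrom_factor(df$chrom), df$pos), , drop = FALSE]
    for (chr in unique(df$chrom)) {
      sub <- df[df$chrom == chr, , drop = FALSE]
      gaps <- diff(sub$pos)
      chain <- cumsum(c(0L, gaps > max_gap_bp))
      for (members in split(seq_len(nrow(sub)), chain)) {
        if (length(members) < min_probes) next
        recs[[length(recs) + 1L]] <- data.frame(
          comparison = comparison, direction = dir, chrom = chr,
          start_pos = sub$pos[members[1L]],
          end_pos = sub$pos[members[length(members)]],
          n_dmps = length(members),
          probe_ids = I(list(sub$probe_id[members])),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(comparison = character(), direction = character(),
               chrom = character(), start_pos = integer(),
               end_pos = integer(), n_dmps = integer(),
               probe_ids = I(list()), stringsAsFactors = FALSE)
  out <- out[order(chrom_factor(out$chrom), out$start_pos, out$direction), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dm_records", "data.frame")
  out
}

#' Annotate DMRs with flanked gene overlaps
#'
#' Each DMR is extended on both sides by `flank_frac` of its own length
#' (`flank_bp = round(flank_frac * (end - start + 1))`, clipped at
#' position 1) and annotated with the symbols of all gene intervals
#' overlapping the flanked interval.
#'
#' @param dmrs A `dm_records` data frame.
#' @param genes Gene model data frame (`chrom`, `start`, `end`, `symbol`),
#'   1-based inclusive.
#' @param flank_frac Flank size as a fraction of DMR length (default 0.2).
#' @return `dmrs` with added `flank_bp` and `genes` (';'-separated
#'   symbols) columns.
#' @export
annotate_dmrs <- function(dmrs, genes, flank_frac = 0.2) {
  stopifnot(inherits(dmrs, "dm_records"),
            all(c("chrom", "start", "end", "symbol") %in% names(genes)))
  if (nrow(dmrs) == 0L) {
    dmrs$flank_bp <- integer(0)
    dmrs$genes <- character(0)
    return(dmrs)
  }
  flank <- round(flank_frac * (dmrs$end_pos - dmrs$start_pos + 1))
  gr_dmr <- GenomicRanges::GRanges(
    dmrs$chrom,
    IRanges::IRanges(pmax(1, dmrs$start_pos - flank),
                     dmrs$end_pos + flank))
  gr_gene <- GenomicRanges::GRanges(
    sub("^chr", "", as.character(genes$chrom)),
    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_dmr, gr_gene)
  sym <- rep("", nrow(dmrs))
  if (length(hits) > 0L) {
    by_dmr <- split(genes$symbol[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
    for (i in names(by_dmr))
      sym[as.integer(i)] <- paste(unique(by_dmr[[i]]), collapse = ";")
  }
  dmrs$flank_bp <- as.integer(flank)
  dmrs$genes <- sym
  dmrs
}

#' Recurrent genes across DMR lists
#'
#' Tallies, for every gene annotated to a DMR, its total number of DMR
#' occurrences and the number of distinct comparison lists it appears in.
#' A gene is recurrent iff it occurs more than once within or between
#' comparisons.
#'
#' @param dmr_lists A single annotated `dm_records` frame or a list of
#'   them (one per comparison).
#' @return Data frame `gene`, `n_total`, `n_comparisons`, `recurrent`,
#'   sorted by decreasing `n_total`.
#' @export
recurrent_genes <- function(dmr_lists) {
  if (inherits(dmr_lists, "data.frame")) dmr_lists <- list(dmr_lists)
  rows <- list()
  for (dmrs in dmr_lists) {
    if (nrow(dmrs) == 0L) next
    if (is.null(dmrs$genes)) stop("DMRs must be annotated first")
    for (i in seq_len(nrow(dmrs))) {
      g <- setdiff(strsplit(dmrs$genes[i], ";", fixed = TRUE)[[1L]], "")
      if (length(g) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, comparison = dmrs$comparison[i],
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(), n_total = integer(),
                      n_comparisons = integer(), recurrent = logical(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  n_total <- table(tab$gene)
  n_comp <- vapply(split(tab$comparison, tab$gene),
                   function(x) length(unique(x)), integer(1))
  out <- data.frame(gene = names(n_total),
                    n_total = as.integer(n_total),
                    n_comparisons = as.integer(n_comp[names(n_total)]),
                    stringsAsFactors = FALSE)
  out$recurrent <- out$n_total > 1L
  out <- out[order(-out$n_total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export DMRs as BED
#'
#' Writes 0-based half-open intervals (explicit conversion from the
#' package's 1-based inclusive coordinates), name =
#' `comparison:direction:genes`.
#'
#' @param dmrs A (preferably annotated) `dm_records` frame.
#' @param path Output BED path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  name <- paste(dmrs$comparison, dmrs$direction,
                if (is.null(dmrs$genes)) "" else dmrs$genes, sep = ":")
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start_pos - 1L,
                    end = dmrs$end_pos, name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
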