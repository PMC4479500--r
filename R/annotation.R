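# Extended probe annotation: manifest I/O, functional categories,
# imprinting resources and ICR interval handling.

MANIFEST_REQUIRED <- c("probe_id", "chrom", "pos", "strand")
MANIFEST_OPTIONAL <- c("gene_symbols", "tss_distance_class", "region_classes",
                       "island", "repeat_class", "mir", "snrna")

#' Load a probe manifest
#'
#' Reads a TSV/CSV probe manifest into a `probe_table`: one row per array
#' probe with its genomic coordinate (1-based position of the target CpG)
#' and precomputed functional annotation columns. Rows are returned sorted
#' by (chromosome, position); duplicated probe ids are rejected.
#'
#' Required columns: `probe_id`, `chrom` (1-22, X, Y; an optional "chr"
#' prefix is stripped), `pos` (1-based), `strand` (+/-). Optional columns
#' (`gene_symbols`, `tss_distance_class`, `region_classes`, `island`,
#' `repeat_class`, `mir`, `snrna`) default to empty/none when absent.
#' `gene_symbols` and `region_classes` are ';'-separated.
#'
#' @param path Path to a tab- or comma-separated manifest with a header.
#' @param sep Field separator; guessed from the header line when `NULL`.
#' @return A `data.frame` of class `probe_table`, sorted by (chrom, pos).
#' @export
load_manifest <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  missing_cols <- setdiff(MANIFEST_REQUIRED, names(df))
  if (length(missing_cols) > 0L)
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  pos_num <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(pos_num)) {
    bad <- which(is.na(pos_num))[1L]
    stop("non-numeric position at manifest line ", bad + 1L,
         " (probe ", df$probe_id[bad], ")")
  }
  df$pos <- as.integer(pos_num)
  probe_table(df)
}

#' Construct a probe table from a data frame
#'
#' Validates, fills optional annotation columns, and sorts by
#' (chromosome, position).
#'
#' @param df A data frame with at least the required manifest columns.
#' @return A `probe_table`.
#' @export
probe_table <- function(df) {
  missing_cols <- setdiff(MANIFEST_REQUIRED, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicated probe_id(s): ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  if (any(df$pos < 1L)) stop("positions must be >= 1 (1-based coordinates)")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  defaults <- list(gene_symbols = "", tss_distance_class = "none",
                   region_classes = "", island = FALSE,
                   repeat_class = "none", mir = FALSE, snrna = FALSE)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df$island <- as.logical(df$island)
  df$mir <- as.logical(df$mir)
  df$snrna <- as.logical(df$snrna)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df <- order_probes(df)
  rownames(df) <- df$probe_id
  class(df) <- c("probe_table", "data.frame")
  df
}

#' Merge overlapping imprinting control regions
#'
#' Overlapping or book-ended ICR intervals (1-based, inclusive) on the same
#' chromosome with the same expressed allele are merged into single
#' intervals. Overlaps between intervals of *conflicting* alleles are kept
#' separate, flagged in the `conflict` column, and reported with a warning.
#'
#' @param icrs Data frame with columns `chrom`, `start`, `end`,
#'   `allele` (one of "P", "M", "unknown").
#' @return Merged data frame (`chrom`, `start`, `end`, `allele`,
#'   `conflict`) sorted by (chrom, start), with attribute `n_raw`.
#' @export
merge_icrs <- function(icrs) {
  stopifnot(all(c("chrom", "start", "end", "allele") %in% names(icrs)))
  if (!all(icrs$allele %in% c("P", "M", "unknown")))
    stop("unknown expressed_allele value; must be P, M or unknown")
  if (any(icrs$end < icrs$start)) stop("ICR with end < start")
  if (nrow(icrs) == 0L) {
    out <- icrs[, c("chrom", "start", "end", "allele")]
    out$conflict <- logical(0)
    attr(out, "n_raw") <- 0L
    class(out) <- c("icr_table", "data.frame")
    return(out)
  }
  icrs$chrom <- sub("^chr", "", as.character(icrs$chrom))
  pieces <- lapply(split(icrs, icrs$allele), function(part) {
    gr <- GenomicRanges::GRanges(part$chrom,
                                 IRanges::IRanges(part$start, part$end))
    red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red),
               end = GenomicRanges::end(red),
               allele = part$allele[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  # conflicting-allele overlap check on the merged set
  gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start, out$end))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  conflict <- logical(nrow(out))
  if (length(hits) > 0L) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    diff_allele <- out$allele[q] != out$allele[s]
    conflict[unique(q[diff_allele])] <- TRUE
    if (any(diff_allele))
      warning("ICR intervals with conflicting expressed alleles overlap; ",
              "kept separate")
  }
  out$conflict <- conflict
  out <- out[order(chrom_factor(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_raw") <- nrow(icrs)
  class(out) <- c("icr_table", "data.frame")
  out
}

#' Bundle imprinting resources
#'
#' Combines an imprinted-gene TSS list with a (merged) validated-ICR
#' interval list into one resource object, optionally computing how many
#' merged ICRs are covered by at least one probe of a probe table.
#'
#' @param imprinted_tss Data frame (`gene`, `chrom`, `tss`, `strand`,
#'   `allele` in P/M).
#' @param icrs Raw ICR data frame; merged via [merge_icrs()].
#' @param probes Optional `probe_table` used to compute ICR coverage.
#' @return A list of class `imprint_resource` with elements
#'   `imprinted_tss`, `icrs`, `n_icrs_merged` and (if `probes` given)
#'   `n_icrs_covered`.
#' @export
imprint_resource <- function(imprinted_tss, icrs, probes = NULL) {
  stopifnot(all(c("gene", "chrom", "tss", "strand", "allele") %in%
                  names(imprinted_tss)))
  if (!all(imprinted_tss$allele %in% c("P", "M")))
    stop("unknown expressed_allele value in imprinted_tss; must be P or M")
  imprinted_tss$chrom <- sub("^chr", "", as.character(imprinted_tss$chrom))
  merged <- if (inherits(icrs, "icr_table")) icrs else merge_icrs(icrs)
  res <- list(imprinted_tss = imprinted_tss, icrs = merged,
              n_icrs_merged = nrow(merged))
  if (!is.null(probes)) {
    gr_icr <- GenomicRanges::GRanges(merged$chrom,
                                     IRanges::IRanges(merged$start, merged$end))
    gr_probe <- GenomicRanges::GRanges(probes$chrom,
                                       IRanges::IRanges(probes$pos, probes$pos))
    res$n_icrs_covered <-
      sum(IRanges::overlapsAny(gr_icr, gr_probe))
  }
  class(res) <- "imprint_resource"
  res
}

# Probes within an upstream window [0, d] bp of a TSS on the gene strand.
upstream_of_tss <- function(probes, tss_df, d) {
  hit <- rep(FALSE, nrow(probes))
  for (i in seq_len(nrow(tss_df))) {
    on_chrom <- probes$chrom == tss_df$chrom[i]
    dist <- if (tss_df$strand[i] == "+")
      tss_df$tss[i] - probes$pos else probes$pos - tss_df$tss[i]
    hit <- hit | (on_chrom & dist >= 0 & dist <= d)
  }
  hit
}

probes_in_icrs <- function(probes, icrs, allele) {
  sel <- icrs[icrs$allele == allele, , drop = FALSE]
  if (nrow(sel) == 0L) return(rep(FALSE, nrow(probes)))
  gr_probe <- GenomicRanges::GRanges(probes$chrom,
                                     IRanges::IRanges(probes$pos, probes$pos))
  gr_icr <- GenomicRanges::GRanges(sel$chrom,
                                   IRanges::IRanges(sel$start, sel$end))
  IRanges::overlapsAny(gr_probe, gr_icr)
}

#' Assign probes to functional genomic categories
#'
#' Builds the extended functional category map used by the enrichment
#' analysis: gene-relative classes copied from the manifest (TSS windows,
#' 5'UTR/EXON1/gene body/3'UTR, CpG island, LINE/SINE repeats, miRNA and
#' snRNA association), imprinting-associated sets, and the X chromosome.
#'
#' A probe is `ICR_P`/`ICR_M` iff its position lies inside a merged ICR of
#' that expressed allele (inclusive bounds). It is `IMPR_{P,M}{200,1500}`
#' iff it lies within 200/1500 bp upstream of the TSS of an imprinted gene
#' of that allele (measured on the annotated gene strand, distance 0
#' counting as inside both windows) *or* inside an ICR of that allele: the
#' two criteria are not mutually exclusive.
#'
#' @param probes A `probe_table`.
#' @param imprint An `imprint_resource` (merged ICRs).
#' @return A named list of class `functional_categories` mapping category
#'   name to a character vector of probe ids, with attribute `universe`.
#' @export
classify_probes <- function(probes, imprint) {
  stopifnot(inherits(probes, "probe_table"),
            inherits(imprint, "imprint_resource"))
  tssc <- probes$tss_distance_class
  region <- strsplit(probes$region_classes, ";", fixed = TRUE)
  has_region <- function(cls)
    vapply(region, function(r) cls %in% r, logical(1))
  icr_p <- probes_in_icrs(probes, imprint$icrs, "P")
  icr_m <- probes_in_icrs(probes, imprint$icrs, "M")
  tss_p <- imprint$imprinted_tss[imprint$imprinted_tss$allele == "P", ,
                                 drop = FALSE]
  tss_m <- imprint$imprinted_tss[imprint$imprinted_tss$allele == "M", ,
                                 drop = FALSE]
  sets <- list(
    TSS200        = tssc == "TSS200",
    TSSAssociated = tssc %in% c("TSS200", "TSS1500"),
    `5'UTR`       = has_region("5'UTR"),
    EXON1         = has_region("EXON1"),
    GENE.BODY     = has_region("GENE.BODY"),
    `3'UTR`       = has_region("3'UTR"),
    ISLAND        = probes$island,
    LINE          = probes$repeat_class == "LINE",
    SINE          = probes$repeat_class == "SINE",
    MIR           = probes$mir,
    snRNA         = probes$snrna,
    ICR_P         = icr_p,
    ICR_M         = icr_m,
    IMPR_P200     = upstream_of_tss(probes, tss_p, 200L) | icr_p,
    IMPR_P1500    = upstream_of_tss(probes, tss_p, 1500L) | icr_p,
    IMPR_M200     = upstream_of_tss(probes, tss_m, 200L) | icr_m,
    IMPR_M1500    = upstream_of_tss(probes, tss_m, 1500L) | icr_m,
    X_CHROM       = probes$chrom == "X"
  )
  out <- lapply(sets, function(keep) probes$probe_id[keep])
  attr(out, "universe") <- probes$probe_id
  class(out) <- "functional_categories"
  out
}

#' Read ICR intervals from TSV
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `allele`.
#' @return Data frame of raw ICR intervals.
#' @export
load_icrs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read an imprinted-gene TSS list from TSV
#'
#' @param path TSV with columns `gene`, `chrom`, `tss`, `strand`, `allele`.
#' @return Data frame of imprinted-gene TSS records.
#' @export
load_imprinted_tss <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
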