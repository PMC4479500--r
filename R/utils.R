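# Shared internal helpers.

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

#' @useDynLib methylseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

chrom_factor <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  bad <- setdiff(unique(chrom), CHROM_LEVELS)
  if (length(bad) > 0L)
    stop("unknown chromosome name(s): ", paste(bad, collapse = ", "))
  factor(chrom, levels = CHROM_LEVELS)
}

order_probes <- function(df) {
  df[order(chrom_factor(df$chrom), df$pos), , drop = FALSE]
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("standard deviation undefined for fewer than 2 samples")
  mu <- rowMeans(x)
  sqrt(pmax(rowSums((x - mu)^2), 0) / (n - 1))
}

# Column medians restricted to a row subset; returns a vector over samples.
col_medians <- function(x, rows = NULL) {
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  apply(x, 2L, stats::median)
}

# Stratified resample with replacement: indices drawn with replacement
# within each group, preserving group sizes. Groups are visited in sorted
# label order so RNG consumption does not depend on factor level order
# (this makes label swaps exactly anti-symmetric downstream).
stratified_resample <- function(groups) {
  idx <- seq_along(groups)
  unlist(lapply(split(idx, as.character(groups)), function(i) {
    i[sample.int(length(i), length(i), replace = TRUE)]
  }), use.names = FALSE)
}

# Cyclic fold assignment within each group after a seeded shuffle; same
# canonical group order as stratified_resample.
stratified_folds <- function(groups, n_folds) {
  fold <- integer(length(groups))
  for (g in split(seq_along(groups), as.character(groups))) {
    g <- g[sample.int(length(g))]
    fold[g] <- rep_len(seq_len(n_folds), length(g))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validates a two-level grouping. Factor level order is preserved (the
# first level is group "A", the reference for the hyperA direction);
# non-factor input gets alphabetical levels.
assert_two_groups <- function(labels) {
  if (!is.factor(labels)) labels <- factor(as.character(labels))
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two group labels required, got: ",
         paste(levels(labels), collapse = ", "))
  if (any(table(labels) == 0L)) stop("both groups must be non-empty")
  labels
}
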