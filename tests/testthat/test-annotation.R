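# Probe manifest handling, functional classification and ICR merging.

test_that("manifest loading sorts by genomic position and validates input", {
  df <- data.frame(
    probe_id = c("p5", "p1", "p3", "p2", "p4"),
    chrom = c("2", "1", "1", "X", "1"),
    pos = c(100L, 500L, 200L, 50L, 900L),
    strand = "+", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- load_manifest(path)
  expect_s3_class(pt, "probe_table")
  expect_equal(pt$probe_id, c("p3", "p1", "p4", "p5", "p2"))
  expect_true(!is.unsorted(as.integer(chrom_order <- factor(
    pt$chrom, levels = c(as.character(1:22), "X", "Y")))))

  # comma-separated files are handled too
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write.table(df, pcsv, sep = ",", quote = FALSE, row.names = FALSE)
  expect_equal(load_manifest(pcsv)$probe_id, pt$probe_id)

  df_dup <- df
  df_dup$probe_id[2L] <- "p5"
  write.table(df_dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_manifest(path), "p5")

  df_bad <- df
  df_bad$pos <- as.character(df_bad$pos)
  df_bad$pos[3L] <- "12x4"
  write.table(df_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_manifest(path), "line 4")

  write.table(df[, c("probe_id", "chrom", "strand")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_manifest(path), "pos")
})

test_that("TSS-window and ICR membership rules follow the upstream-window definition", {
  # gene G1: + strand, TSS 10000, paternally expressed
  # gene G2: - strand, TSS 30000, maternally expressed
  tss <- data.frame(gene = c("G1", "G2"), chrom = "1",
                    tss = c(10000L, 30000L), strand = c("+", "-"),
                    allele = c("P", "M"), stringsAsFactors = FALSE)
  icr <- data.frame(chrom = "1", start = 50000L, end = 51000L,
                    allele = "P", stringsAsFactors = FALSE)
  probes <- toy_probes(c(
    9850,   # 150 bp upstream of G1 (+): in P200 and P1500
    9000,   # 1000 bp upstream of G1: in P1500 only
    10010,  # downstream of G1: in neither window
    30150,  # 150 bp upstream of G2 (-): in M200
    29900,  # downstream of G2 (-): in neither
    50500,  # inside the ICR: ICR_P and (by the or-rule) IMPR_P*
    70000)) # nowhere
  res <- imprint_resource(tss, icr)
  cats <- classify_probes(probes, res)

  expect_setequal(cats$IMPR_P200, c("p001", "p006"))
  expect_setequal(cats$IMPR_P1500, c("p001", "p002", "p006"))
  expect_setequal(cats$IMPR_M200, "p004")
  expect_setequal(cats$ICR_P, "p006")
  expect_length(cats$ICR_M, 0L)
  # probe near a TSS but outside any ICR is not an ICR probe
  expect_false("p001" %in% cats$ICR_P)
  # containment invariants
  expect_true(all(cats$IMPR_P200 %in% cats$IMPR_P1500))
  expect_true(all(cats$IMPR_M200 %in% cats$IMPR_M1500))
  expect_true(all(cats$TSS200 %in% cats$TSSAssociated))
  # distance 0 (at the TSS) counts as inside both windows
  at_tss <- classify_probes(toy_probes(10000L), res)
  expect_equal(at_tss$IMPR_P200, "p001")
})

test_that("functional classification matches a brute-force interval check", {
  set.seed(42)
  pos <- sort(sample.int(5000L, 20L))
  probes <- toy_probes(pos)
  icr <- data.frame(chrom = "1",
                    start = c(500L, 3000L), end = c(1200L, 3600L),
                    allele = c("P", "M"), stringsAsFactors = FALSE)
  res <- imprint_resource(
    data.frame(gene = character(), chrom = character(), tss = integer(),
               strand = character(), allele = character()),
    icr)
  cats <- classify_probes(probes, res)
  brute_in <- function(p, iv) any(p >= iv$start & p <= iv$end)
  for (i in seq_len(nrow(probes))) {
    expect_equal(probes$probe_id[i] %in% cats$ICR_P,
                 brute_in(probes$pos[i], icr[1L, ]))
    expect_equal(probes$probe_id[i] %in% cats$ICR_M,
                 brute_in(probes$pos[i], icr[2L, ]))
  }
})

test_that("ICR merging joins overlapping and book-ended intervals of one allele", {
  raw <- data.frame(chrom = "11",
                    start = c(100L, 150L), end = c(200L, 300L),
                    allele = "M", stringsAsFactors = FALSE)
  merged <- merge_icrs(raw)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 300L)

  disjoint <- data.frame(chrom = "11",
                         start = c(100L, 500L), end = c(200L, 600L),
                         allele = "M", stringsAsFactors = FALSE)
  expect_equal(nrow(merge_icrs(disjoint)), 2L)

  booked <- data.frame(chrom = "11",
                       start = c(100L, 201L), end = c(200L, 300L),
                       allele = "P", stringsAsFactors = FALSE)
  expect_equal(nrow(merge_icrs(booked)), 1L)

  conflict <- data.frame(chrom = "11",
                         start = c(100L, 150L), end = c(200L, 300L),
                         allele = c("P", "M"), stringsAsFactors = FALSE)
  expect_warning(out <- merge_icrs(conflict), "conflicting")
  expect_equal(nrow(out), 2L)
  expect_true(all(out$conflict))

  expect_error(merge_icrs(data.frame(chrom = "1", start = 10L, end = 5L,
                                     allele = "Q")), "allele")
})

test_that("ICR merging equals the position-flag union oracle and ignores input order", {
  set.seed(7)
  raw <- data.frame(
    chrom = sample(c("1", "2"), 50L, replace = TRUE),
    start = sample.int(800L, 50L, replace = TRUE),
    allele = sample(c("P", "M"), 50L, replace = TRUE),
    stringsAsFactors = FALSE)
  raw$end <- raw$start + sample.int(120L, 50L, replace = TRUE)
  merged <- suppressWarnings(merge_icrs(raw))
  oracle <- oracle_merge_intervals(raw)
  got <- merged[order(merged$chrom, merged$allele, merged$start),
                c("chrom", "start", "end", "allele")]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(as.data.frame(got), oracle)

  shuffled <- raw[sample.int(nrow(raw)), ]
  merged2 <- suppressWarnings(merge_icrs(shuffled))
  expect_equal(as.data.frame(merged2), as.data.frame(merged))
})

test_that("ICR coverage counts merged intervals containing at least one probe", {
  probes <- toy_probes(c(100L, 5000L))
  icr <- data.frame(chrom = "1",
                    start = c(50L, 2000L, 9000L),
                    end = c(150L, 2500L, 9500L),
                    allele = "P", stringsAsFactors = FALSE)
  res <- imprint_resource(
    data.frame(gene = character(), chrom = character(), tss = integer(),
               strand = character(), allele = character()),
    icr, probes = probes)
  expect_equal(res$n_icrs_merged, 3L)
  expect_equal(res$n_icrs_covered, 1L)
})
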