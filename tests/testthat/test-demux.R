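test_that("barcode fields are exact substrings of read 2", {
  lay <- read_layout(data.frame(
    role = c("umi", "x_barcode", "y_barcode"),
    start = c(0, 10, 18), length = c(10, 8, 8)))
  f <- extract_barcodes(paste0("ACGTACGTAC", "AAAAAAAA", "CCCCCCCC"), lay)
  expect_equal(f$umi, "ACGTACGTAC")
  expect_equal(f$x_seq, "AAAAAAAA")
  expect_equal(f$y_seq, "CCCCCCCC")
  expect_false(f$short)
  expect_true(is.na(f$z_seq))

  short <- extract_barcodes("ACGT", lay)
  expect_true(short$short)
  expect_true(is.na(short$umi))
})

test_that("linker segments do not disturb barcode extraction", {
  plain <- read_layout(data.frame(
    role = c("umi", "x_barcode", "y_barcode"),
    start = c(0, 10, 18), length = c(10, 8, 8)))
  linked <- read_layout(data.frame(
    role = c("umi", "x_barcode", "linker", "y_barcode"),
    start = c(0, 10, 18, 33), length = c(10, 8, 15, 8)))
  umi <- "GGGGGTTTTT"; x <- "ACGTACGT"; y <- "TGCATGCA"
  r_plain <- paste0(umi, x, y)
  r_linked <- paste0(umi, x, strrep("A", 15), y)
  a <- extract_barcodes(r_plain, plain)
  b <- extract_barcodes(r_linked, linked)
  expect_equal(a[, c("umi", "x_seq", "y_seq")], b[, c("umi", "x_seq", "y_seq")])
})

test_that("Hamming correction resolves unique near-matches and drops the rest", {
  lg <- toy_legend()
  lay <- default_read_layout()
  exact <- build_read2("ACGTACGTAC", "CCCCAAAA", "AAATTTTT", "AGAGAGAG")
  one_off <- build_read2("ACGTACGTAC", "CCCCAAAT", "AAATTTTT", "AGAGAGAG")
  two_off <- build_read2("ACGTACGTAC", "CCCCAATT", "AAATTTTT", "AGAGAGAG")
  a <- correct_and_assign(extract_barcodes(c(exact, one_off, two_off), lay), lg)
  expect_equal(a$status, c("valid", "valid", "invalid_x"))
  expect_equal(a$x_idx[1:2], c(1L, 1L))
  expect_equal(a$y_idx[1:2], c(1L, 1L))
  expect_equal(a$well_id[1:2], c("B1", "B1"))
  # distance >= 2 from every entry: confirmed by brute force
  expect_true(min(hamming_distances("CCCCAATT",
                                    lg$x$sequence)) >= 2)
})

test_that("correction agrees with exhaustive minimum-distance search", {
  set.seed(101)
  lg <- make_legend(n_x = 8, n_y = 8, wells = c("A1", "B1"),
                    barcodes_per_well = 2, min_hamming = 3, seed = 5)
  lay <- default_read_layout()
  n <- 2000
  # random reads: mix of mutated legend barcodes and pure noise
  mutate <- function(pool, k) {
    s <- sample(pool, k, replace = TRUE)
    n_mut <- sample(0:3, k, replace = TRUE)
    for (i in which(n_mut > 0)) {
      pos <- sample(8, n_mut[i])
      ch <- strsplit(s[i], "")[[1]]
      ch[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
      s[i] <- paste(ch, collapse = "")
    }
    s
  }
  r2 <- build_read2(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = ""), ""),
    mutate(lg$x$sequence, n), mutate(lg$y$sequence, n), mutate(lg$z$sequence, n))
  f <- extract_barcodes(r2, lay)
  a <- correct_and_assign(f, lg, max_hamming = 1)
  for (i in sample(n, 300)) {
    ox <- oracle_match(f$x_seq[i], lg$x$sequence, 1)
    oy <- oracle_match(f$y_seq[i], lg$y$sequence, 1)
    oz <- oracle_match(f$z_seq[i], lg$z$sequence, 1)
    expect_identical(a$x_idx[i],
                     if (is.na(ox)) NA_integer_ else lg$x$index[ox])
    expect_identical(a$y_idx[i],
                     if (is.na(oy)) NA_integer_ else lg$y$index[oy])
    expect_identical(a$well_id[i],
                     if (is.na(oz)) NA_character_ else lg$z$well[oz])
    expect_identical(a$status[i] == "valid",
                     !is.na(ox) && !is.na(oy) && !is.na(oz))
  }
})

test_that("every read lands in exactly one status class", {
  cfg <- tiny_config(error_rate = 0.05)   # high error rate: all classes hit
  tr <- simulate_truth_counts(cfg)
  sim <- simulate_reads(tr, cfg)
  r2 <- c(sim$r2, "ACGT")                 # plus one short read
  a <- correct_and_assign(
    extract_barcodes(r2, cfg$read_layout), sim$legend)
  expect_equal(sum(unlist(table(a$status))), length(r2))
  expect_setequal(unique(a$status),
                  intersect(c("valid", "invalid_x", "invalid_y", "invalid_z",
                              "short"), unique(a$status)))
  expect_gt(sum(a$status == "short"), 0)
})

test_that("well/library mismatches are flagged as crosstalk", {
  lg <- toy_legend()
  lay <- default_read_layout()
  r2 <- c(build_read2("AAAAACGTAC", "AAAAAAAA", "TTTTTTTT", "ACACACAC"),
          build_read2("AAAAACGTAC", "AAAAAAAA", "TTTTTTTT", "AGAGAGAG"))
  a <- correct_and_assign(extract_barcodes(r2, lay), lg)
  ex <- list(A1 = "A1", B1 = "B1")
  out <- filter_crosstalk(a, "A1", ex)
  expect_equal(out$status, c("valid", "crosstalk"))
  # without a z segment the filter passes everything through
  lay_nz <- default_read_layout(with_z = FALSE)
  lg_nz <- toy_legend(with_z = FALSE)
  a2 <- correct_and_assign(extract_barcodes(
    build_read2("AAAAACGTAC", "AAAAAAAA", "TTTTTTTT"), lay_nz), lg_nz)
  expect_equal(filter_crosstalk(a2, "A1", ex)$status, "valid")
})

test_that("gene assignment requires a unique exact prefix match", {
  set.seed(7)
  shared <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
  ref <- c("geneA|tx1|exonic" = paste0(
             paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = ""), shared),
           "geneB|tx1|exonic" = paste0(
             paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = ""), shared))
  unique_read <- substr(ref[1], 10, 59)       # unique to geneA
  shared_read <- substr(shared, 1, 50)        # present in both genes
  nonsense <- strrep("A", 50)
  g <- assign_gene(c(unique_read, shared_read, nonsense), ref)
  expect_equal(g$gene, c("geneA", NA, NA))
  expect_equal(g$assigned, c(TRUE, FALSE, FALSE))
})

test_that("intronic reads are counted only when requested", {
  ref <- simulate_reference(5, transcript_len = 200, intron_len = 200,
                            seed = 3)
  intr <- ref[grepl("intronic", names(ref))][1]
  exon <- ref[grepl("exonic", names(ref))][1]
  reads <- data.table::data.table(
    read_id = c("r1", "r2"),
    well_id = "A1", x_idx = 1L, y_idx = 1L,
    umi = c("AAAAAAAAAA", "GGGGGGGGGG"),
    status = "valid",
    gene = "gene001",
    region = c("exonic", "intronic"))
  with_intr <- digital_expression(reads, include_intronic = TRUE)
  wo_intr <- digital_expression(reads, include_intronic = FALSE)
  expect_equal(sum(with_intr$counts), 2)
  expect_equal(sum(wo_intr$counts), 1)
  # reference sanity: intron and exon records resolve to the same gene
  g <- assign_gene(c(substr(exon, 1, 40), substr(intr, 1, 40)), ref)
  expect_equal(g$gene, c("gene001", "gene001"))
  expect_equal(g$region, c("exonic", "intronic"))
})
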