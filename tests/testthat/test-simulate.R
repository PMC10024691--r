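test_that("generated legends respect the pairwise Hamming floor", {
  lg <- make_legend(n_x = 36, n_y = 36,
                    wells = paste0(rep(LETTERS[1:3], each = 3), 1:3),
                    barcodes_per_well = 4, min_hamming = 3, seed = 1)
  expect_equal(nrow(lg$x), 36)
  expect_equal(nrow(lg$y), 36)
  expect_equal(nrow(lg$z), 36)
  for (ax in list(lg$x$sequence, lg$y$sequence, lg$z$sequence)) {
    d <- hamming_distances(ax, ax)
    diag(d) <- Inf
    expect_gte(min(d), 3)
  }
  expect_equal(unname(table(lg$z$well)[1]), 4L, ignore_attr = TRUE)
})

test_that("legend generation is deterministic and min_hamming=1 is lax", {
  a <- make_legend(n_x = 10, n_y = 10, wells = c("A1", "B1"), seed = 99)
  b <- make_legend(n_x = 10, n_y = 10, wells = c("A1", "B1"), seed = 99)
  expect_identical(a, b)
  lax <- make_legend(n_x = 20, n_y = 20, wells = NULL, min_hamming = 1,
                     barcode_len = 4, seed = 2)
  expect_equal(nrow(lax$x), 20)   # any distinct sequences accepted
  expect_error(make_legend(n_x = 30, n_y = 2, wells = NULL, barcode_len = 2,
                           seed = 3), "infeasible")
})

test_that("legend tables round-trip through CSV", {
  lg <- make_legend(n_x = 6, n_y = 6, wells = c("A1", "B1"), seed = 4)
  f <- tempfile(fileext = ".csv")
  write_barcode_legend(lg, f)
  lg2 <- read_barcode_legend(f)
  expect_equal(lg2$x, lg$x)
  expect_equal(lg2$z, lg$z)
})

test_that("background spots are silent when the ambient rate is zero", {
  cfg <- tiny_config(seed = 21, background_lambda = 0)
  tr <- simulate_truth_counts(cfg)
  bg <- !tr$counts$spots$tissue_truth
  expect_equal(sum(tr$counts$counts[, bg]), 0)
  expect_gt(sum(tr$counts$counts[, !bg]), 0)
})

test_that("expected spot totals follow the configured means and stripes", {
  rf <- c(1, 1, 2, 1, 0.5, 1, 1, 1)
  cfg <- tiny_config(seed = 22, n_genes = 50, background_lambda = 0.5,
                     gene_mean_meanlog = log(1), gene_mean_sdlog = 0,
                     contamination_gene_fraction = 0,
                     stripe_row_factors = rf)
  tr <- simulate_truth_counts(cfg)
  sp <- tr$counts$spots
  tot <- Matrix::colSums(tr$counts$counts)
  mu_tissue <- 50 * (1 + 0.5)     # per-gene mean 1 + ambient 0.5
  for (y in c(2L, 4L)) {          # a doubled and a halved row
    sel <- sp$tissue_truth & sp$y_idx == y
    expected <- mu_tissue * rf[y + 1L]
    got <- mean(tot[sel])
    se <- sqrt(expected / sum(sel))
    expect_lt(abs(got - expected), 4 * se)
  }
})

test_that("stripe-free runs sit at the Poisson-only variation level", {
  # full tissue coverage: row variation then reflects noise and stripes only
  cfg0 <- tiny_config(seed = 23, n_genes = 50, tissue_radius_frac = 5)
  cfg1 <- tiny_config(seed = 23, n_genes = 50, tissue_radius_frac = 5,
                      stripe_row_factors = seq(0.5, 2, length.out = 8))
  cv0 <- stripe_metric(simulate_truth_counts(cfg0)$counts)$row_cv
  cv1 <- stripe_metric(simulate_truth_counts(cfg1)$counts)$row_cv
  expect_gt(cv1, 3 * cv0)
})

test_that("identical configs and seeds give byte-identical outputs", {
  cfg <- tiny_config(seed = 24, error_rate = 0.01, contamination_rate = 0.05)
  t1 <- simulate_truth_counts(cfg); t2 <- simulate_truth_counts(cfg)
  expect_identical(as.matrix(t1$counts$counts), as.matrix(t2$counts$counts))
  s1 <- simulate_reads(t1, cfg); s2 <- simulate_reads(t2, cfg)
  expect_identical(s1$r1, s2$r1)
  expect_identical(s1$r2, s2$r2)
  cfg_img <- tiny_config(seed = 24, nuclei_per_area = 40)
  i1 <- render_images(cfg_img); i2 <- render_images(cfg_img)
  expect_identical(i1$alignment$nuclei, i2$alignment$nuclei)
  expect_identical(i1$hires$nuclei, i2$hires$nuclei)
})

test_that("written FASTQ files reproduce the in-memory reads", {
  cfg <- tiny_config(seed = 25)
  tr <- simulate_truth_counts(cfg)
  sim <- simulate_reads(tr, cfg)
  f <- tempfile(fileext = ".fastq.gz")
  write_fastq(sim$r2, f)
  back <- Biostrings::readDNAStringSet(f, format = "fastq")
  expect_equal(unname(as.character(back)), unname(sim$r2))
  expect_equal(sub("\\s.*", "", names(back)), names(sim$r2))
})

test_that("single-error barcodes are always recovered with a separated legend", {
  cfg <- tiny_config(seed = 26, error_rate = 0.01)
  tr <- simulate_truth_counts(cfg)
  sim <- simulate_reads(tr, cfg)
  f <- extract_barcodes(sim$r2, cfg$read_layout)
  a <- correct_and_assign(f, sim$legend)
  true_x <- sim$legend$x$sequence[match(sim$reads$x_idx, sim$legend$x$index)]
  one_err <- which(mapply(function(obs, tru)
    sum(utf8ToInt(obs) != utf8ToInt(tru)) == 1L, f$x_seq, true_x))
  expect_gt(length(one_err), 0)
  # min pairwise distance 3 makes single errors uniquely correctable
  expect_true(all(a$x_idx[one_err] == sim$reads$x_idx[one_err]))
})

test_that("a planted contamination rate is recovered from the z-composition", {
  cfg <- tiny_config(seed = 27, layout = tiny_layout(n = 6, areas = 2),
                     contamination_rate = 0.07, reads_per_umi = 3L,
                     n_genes = 40)
  tr <- simulate_truth_counts(cfg)
  sim <- simulate_reads(tr, cfg)
  res <- reads_to_counts(NULL, sim$r2, sim$legend, cfg$read_layout,
                         spatial_only = TRUE, library_id = sim$reads$library)
  wc <- well_composition(res$reads)
  n <- nrow(sim$reads)
  ci <- qbinom(c(0.005, 0.995), n, 0.07) / n * 100
  est <- sum(wc$counts * (matrix(rownames(wc$counts), nrow(wc$counts),
                                 ncol(wc$counts)) != matrix(colnames(wc$counts),
                                 nrow(wc$counts), ncol(wc$counts), byrow = TRUE))) /
    sum(wc$counts) * 100
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
})

test_that("rendered images carry the frame and tissue contrast", {
  cfg0 <- tiny_config(seed = 28, nuclei_per_area = 0)
  img0 <- render_images(cfg0)
  expect_gt(max(img0$alignment$marker), 0.5)      # frame present
  expect_lt(max(img0$hires$nuclei), cfg0$tissue_background + 0.3)
  cfg <- tiny_config(seed = 29, nuclei_per_area = 120)
  img <- render_images(cfg)
  tr <- simulate_truth_counts(cfg)
  proj <- project_spots(tr$grid, img$transforms$grid_to_alignment)
  means <- spot_mean_intensity(img$alignment$nuclei, proj)
  sp <- tr$counts$spots
  m <- means[sp$spot_id]
  expect_gt(mean(m[sp$tissue_truth]), mean(m[!sp$tissue_truth]) + 0.05)
})

test_that("a full simulated run writes every artefact to disk", {
  cfg <- tiny_config(seed = 30, nuclei_per_area = 30)
  out <- file.path(tempdir(), "simrun")
  res <- simulate_run(cfg, out)
  files <- c("R1.fastq.gz", "R2.fastq.gz", "legend.csv", "layout.yaml",
             "truth_reads.tsv", "truth_counts.mtx", "reference.fasta",
             "alignment_nuclei.tiff", "grid_to_alignment.json")
  expect_true(all(file.exists(file.path(out, files))))
  tf <- read_affine_json(file.path(out, "grid_to_alignment.json"))
  expect_equal(unclass(tf), unclass(res$images$transforms$grid_to_alignment),
               ignore_attr = TRUE)
  unlink(out, recursive = TRUE)
})
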