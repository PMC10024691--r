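make_counts <- function(m, x_idx = NULL, y_idx = NULL) {
  n <- ncol(m)
  if (is.null(x_idx)) x_idx <- seq_len(n) - 1L
  if (is.null(y_idx)) y_idx <- rep(0L, n)
  ids <- sprintf("A1_x%02d_y%02d", x_idx, y_idx)
  colnames(m) <- ids
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  spot_counts(m, data.frame(spot_id = ids, well_id = "A1",
                            x_idx = x_idx, y_idx = y_idx))
}

test_that("tissue flagging thresholds spot intensities", {
  cm <- make_counts(matrix(1, 2, 4))
  flagged <- flag_tissue_spots(cm, c(0, 0, 100, 100), threshold = 50)
  expect_equal(unname(as.logical(flagged$spots$tissue)), c(F, F, T, T))
  all_tissue <- flag_tissue_spots(cm, c(0, 0, 100, 100), threshold = 0)
  expect_true(all(all_tissue$spots$tissue))
  auto <- flag_tissue_spots(cm, c(0, 1, 99, 100))
  expect_equal(unname(as.logical(auto$spots$tissue)), c(F, F, T, T))
  expect_error(flag_tissue_spots(cm, c(1, 2)), "one finite intensity")
})

test_that("background gene threshold is mu_b + 2*sqrt(mu_b)", {
  # 4 background spots with mean 4 -> t_g = 8; tissue means 9 (kept) and 7
  m <- rbind(kept  = c(4, 4, 4, 4, 9, 9, 9, 9),
             culled = c(4, 4, 4, 4, 7, 7, 7, 7),
             zerobg = c(0, 0, 0, 0, 1, 1, 1, 1))
  cm <- make_counts(m)
  mask <- rep(c(FALSE, TRUE), each = 4)
  bf <- background_gene_filter(cm, tissue_mask = mask)
  expect_equal(bf$t_g[c("kept", "culled", "zerobg"), 1],
               c(kept = 8, culled = 8, zerobg = 0))
  expect_equal(bf$keep[c("kept", "culled", "zerobg")],
               c(kept = TRUE, culled = FALSE, zerobg = TRUE))
})

test_that("filter keep-threshold is monotone in the background mean", {
  mu <- seq(0, 20, by = 0.5)
  tg <- mu + 2 * sqrt(mu)
  expect_true(all(diff(tg) > 0))
})

test_that("filter decisions ignore spot ordering", {
  cfg <- tiny_config(seed = 12, background_lambda = 2,
                     gene_mean_meanlog = log(20), gene_mean_sdlog = 0,
                     contamination_gene_fraction = 0.5, n_genes = 30)
  tr <- simulate_truth_counts(cfg)
  cm <- tr$counts
  mask <- cm$spots$tissue_truth
  base <- background_gene_filter(cm, tissue_mask = mask)
  perm <- sample(ncol(cm$counts))
  cm2 <- spot_counts(cm$counts[, perm], cm$spots[perm, ])
  expect_equal(background_gene_filter(cm2, tissue_mask = mask[perm])$keep,
               base$keep)
})

test_that("planted ambient genes are removed and tissue genes kept", {
  hits <- misses <- 0
  for (seed in 1:5) {
    cfg <- tiny_config(seed = seed, background_lambda = 2,
                       gene_mean_meanlog = log(20), gene_mean_sdlog = 0,
                       contamination_gene_fraction = 0.5, n_genes = 40)
    tr <- simulate_truth_counts(cfg)
    bf <- background_gene_filter(tr$counts,
                                 tissue_mask = tr$counts$spots$tissue_truth)
    correct <- bf$keep != tr$gene_info$is_contamination
    hits <- hits + sum(correct); misses <- misses + sum(!correct)
  }
  expect_gte(hits / (hits + misses), 0.99)
})

test_that("normalization equalizes spot totals and log keeps zeros", {
  m <- matrix(c(60, 40, 0, 150, 50, 0), nrow = 3)  # totals 100, 200
  cm <- make_counts(m)
  nm <- normalize_spots(cm, target_sum = 100)
  expect_equal(unname(Matrix::colSums(nm$counts)), c(100, 100))
  expect_equal(as.numeric(nm$counts[3, ]), c(0, 0))
  lg <- normalize_spots(cm, target_sum = 100, log_transform = TRUE)
  expect_equal(as.numeric(lg$counts[3, ]), c(0, 0))
  expect_equal(as.numeric(lg$counts[1, 1]), log1p(60))
  # default target: median of totals
  nm2 <- normalize_spots(cm)
  expect_equal(unname(Matrix::colSums(nm2$counts)), c(150, 150))
})

test_that("zero-total spots are dropped with a message", {
  m <- matrix(c(5, 5, 0, 0), nrow = 2)
  cm <- make_counts(m)
  expect_message(out <- normalize_spots(cm), "zero-total")
  expect_equal(ncol(out$counts), 1L)
  expect_error(normalize_spots(make_counts(matrix(0, 2, 2))), "all-zero")
})

test_that("stripe metric matches its closed form", {
  # uniform grid -> CV 0
  u <- make_counts(matrix(1, 2, 4), x_idx = c(0L, 1L, 0L, 1L),
                   y_idx = c(0L, 0L, 1L, 1L))
  expect_equal(stripe_metric(u)$row_cv, 0)
  expect_equal(stripe_metric(u)$col_cv, 0)
  # one doubled row in a 2-row grid: row means {2mu, mu}, population sd
  # mu/2, mean 3mu/2 -> CV exactly 1/3
  d <- make_counts(matrix(c(2, 2, 1, 1), nrow = 1),
                   x_idx = c(0L, 1L, 0L, 1L), y_idx = c(0L, 0L, 1L, 1L))
  expect_equal(stripe_metric(d)$row_cv, 1 / 3, tolerance = 1e-12)
  expect_equal(stripe_metric(d)$col_cv, 0)
  # single row is degenerate and reported as 0
  s1 <- make_counts(matrix(c(1, 5), nrow = 1), x_idx = c(0L, 1L),
                    y_idx = c(0L, 0L))
  expect_equal(stripe_metric(s1)$row_cv, 0)
})

test_that("injected stripe factors raise the row CV and normalization removes it", {
  rf <- seq(0.5, 2, length.out = 8)
  cfg <- tiny_config(seed = 14, stripe_row_factors = rf)
  cfg0 <- tiny_config(seed = 14)
  striped <- simulate_truth_counts(cfg)$counts
  clean <- simulate_truth_counts(cfg0)$counts
  pre <- stripe_metric(striped)$row_cv
  expect_gt(pre, stripe_metric(clean)$row_cv)
  post <- stripe_metric(normalize_spots(striped))$row_cv
  expect_lt(post, pre / 5)
})

test_that("saturation at fraction 1 equals the full run and curves rise", {
  cfg <- tiny_config(seed = 15, reads_per_umi = 4L)
  tr <- simulate_truth_counts(cfg)
  sim <- simulate_reads(tr, cfg)
  res <- reads_to_counts(sim$r1, sim$r2, sim$legend, cfg$read_layout,
                         reference = sim$reference)
  sat <- subsample_saturation(res$reads, fractions = c(0.25, 0.5, 1),
                              seed = 1)
  expect_equal(sat$median_umis_per_spot[3],
               median(res$counts$spots$total_umis))
  expect_equal(sat$median_genes_per_spot[3],
               median(res$counts$spots$n_genes))
  expect_true(all(diff(sat$median_umis_per_spot) >= 0))
  expect_true(all(diff(sat$median_genes_per_spot) >= 0))
  expect_error(subsample_saturation(res$reads, fractions = c(0, 0.5)),
               "fractions")
  expect_error(subsample_saturation(res$reads, fractions = 1.5), "fractions")
})

test_that("duplicate-heavy libraries stay near-saturated at half depth", {
  cfg <- tiny_config(seed = 16, reads_per_umi = 10L, n_genes = 15)
  tr <- simulate_truth_counts(cfg)
  sim <- simulate_reads(tr, cfg)
  res <- reads_to_counts(sim$r1, sim$r2, sim$legend, cfg$read_layout,
                         reference = sim$reference)
  sat <- subsample_saturation(res$reads, fractions = c(0.5, 1), seed = 2)
  # expected recovery 1 - (1-f)^d = 1 - 0.5^10 = 0.999
  expect_gte(sat$median_umis_per_spot[1],
             0.85 * sat$median_umis_per_spot[2])
})

test_that("marker presence reports detected fractions", {
  m <- matrix(c(5, 0, 2), nrow = 3,
              dimnames = list(c("Alb", "Ins1", "Nphs2"), NULL))
  cm <- make_counts(m)
  sets <- list(liver = c("Alb"), kidney = c("NPHS2", "Umod"),
               pancreas = c("Ins1"))
  mp <- marker_presence(cm, sets)
  expect_equal(unname(mp), c(1, 0.5, 0))   # Ins1 present but zero count
  expect_error(marker_presence(cm, list(empty = character(0))),
               "empty marker set")
})

test_that("pseudobulk correlation behaves at the extremes", {
  cfg <- tiny_config(seed = 17)
  tr <- simulate_truth_counts(cfg)
  pb <- Matrix::rowSums(tr$counts$counts)
  self <- pseudobulk_correlate(tr$counts,
                               data.frame(gene = names(pb), self = as.numeric(pb)))
  expect_equal(unname(self$r["self"]), 1, tolerance = 1e-12)
  expect_equal(self$method, "cpm")
  set.seed(9)
  rnd <- data.frame(gene = sprintf("gene%03d", 1:1000),
                    noise = rexp(1000))
  pb2 <- setNames(rexp(1000), rnd$gene)
  r <- pseudobulk_correlate(pb2, rnd)
  expect_lt(abs(unname(r$r["noise"])), 0.1)
  expect_error(pseudobulk_correlate(pb2[1], rnd[1, ]), "shared genes")
})

test_that("pseudobulk of the truth equals the generator's gene totals", {
  cfg <- tiny_config(seed = 18)
  tr <- simulate_truth_counts(cfg)
  sim <- simulate_reads(tr, cfg)
  res <- reads_to_counts(sim$r1, sim$r2, sim$legend, cfg$read_layout,
                         reference = sim$reference)
  pb <- Matrix::rowSums(res$counts$counts)
  truth_totals <- Matrix::rowSums(tr$counts$counts)
  truth_totals <- truth_totals[truth_totals > 0]
  expect_equal(pb[names(truth_totals)], truth_totals)
})
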