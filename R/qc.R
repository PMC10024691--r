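#' Flag tissue-covered spots from nuclear-stain intensity
#'
#' Spots are called tissue when their mean nuclear-stain (e.g. DAPI)
#' intensity over the projected spot polygon reaches a threshold.
#' `threshold = "otsu"` picks the cut automatically from the bimodal
#' spot-mean distribution.
#'
#' @param counts A [spot_counts()].
#' @param dapi_means Numeric vector of per-spot mean intensities, named
#'   by `spot_id` (see [spot_mean_intensity()]) or in spot order.
#' @param threshold Numeric cutoff, or `"otsu"` (default).
#' @return The `spot_counts` with the `tissue` metadata column set; the
#'   used threshold is attached as attribute `threshold` of that column's
#'   logical mask, retrievable via `attr(flag_tissue_spots(...)$spots$tissue,
#'   "threshold")`.
#' @export
flag_tissue_spots <- function(counts, dapi_means, threshold = "otsu") {
  stopifnot(inherits(counts, "spot_counts"))
  if (!is.null(names(dapi_means)))
    dapi_means <- dapi_means[counts$spots$spot_id]
  if (length(dapi_means) != nrow(counts$spots) || anyNA(dapi_means))
    stop("need one finite intensity per spot", call. = FALSE)
  th <- if (identical(threshold, "otsu")) .otsu_1d(dapi_means)
        else as.numeric(threshold)
  mask <- dapi_means >= th
  attr(mask, "threshold") <- th
  counts$spots$tissue <- mask
  counts
}

#' Poisson background filter for ambient / cross-contamination genes
#'
#' Spots without underlying tissue measure ambient contamination. For
#' each gene the mean count over background spots, `mu_b`, defines a
#' keep threshold `t_g = mu_b + 2 * sqrt(mu_b)` (mean plus twice the
#' Poisson standard deviation). A gene is kept in a sample when its mean
#' over tissue spots exceeds `t_g`; with several samples, the combined
#' rule keeps a gene detected above background in at least one sample.
#'
#' @param counts A [spot_counts()] or a list of them (one per sample).
#' @param tissue_mask Logical tissue mask per sample (vector or list);
#'   defaults to the `tissue` metadata column.
#' @return List with `keep` (combined logical vector over genes),
#'   `per_sample` (logical matrix genes x samples), `mu_b`, `t_g`
#'   (matrices genes x samples). If a sample has no background spots the
#'   filter is disabled for it with a warning (all genes kept).
#' @export
background_gene_filter <- function(counts, tissue_mask = NULL) {
  if (inherits(counts, "spot_counts")) counts <- list(counts)
  if (!is.null(tissue_mask) && !is.list(tissue_mask))
    tissue_mask <- list(tissue_mask)
  genes <- sort(unique(unlist(lapply(counts, function(x) rownames(x$counts)))))
  ns <- length(counts)
  mu_b <- t_g <- matrix(NA_real_, length(genes), ns,
                        dimnames = list(genes, names(counts)))
  keep_s <- matrix(TRUE, length(genes), ns, dimnames = list(genes, names(counts)))
  for (s in seq_len(ns)) {
    x <- counts[[s]]
    mask <- if (!is.null(tissue_mask)) tissue_mask[[s]] else x$spots$tissue
    if (is.null(mask) || all(is.na(mask)))
      stop("no tissue mask; run flag_tissue_spots() first", call. = FALSE)
    mask <- as.logical(mask)
    gi <- match(rownames(x$counts), genes)
    if (!any(!mask)) {
      warning("sample ", s, " has no background spots; filter disabled")
      next
    }
    mb <- Matrix::rowMeans(x$counts[, !mask, drop = FALSE])
    tg <- mb + 2 * sqrt(mb)
    tm <- Matrix::rowMeans(x$counts[, mask, drop = FALSE])
    mu_b[gi, s] <- mb
    t_g[gi, s] <- tg
    ks <- rep(FALSE, length(genes))   # genes absent from a sample: not kept there
    ks[gi] <- tm > tg
    keep_s[, s] <- ks
  }
  list(keep = rowSums(keep_s, na.rm = TRUE) > 0,
       per_sample = keep_s, mu_b = mu_b, t_g = t_g)
}

#' Normalize spots by their total counts
#'
#' Scales every spot to a common total (default: the median of spot
#' totals), which removes channel-wise "stripe" artifacts caused by
#' unequal flow, then optionally applies `log(1 + x)`. Spots with zero
#' totals are dropped with a message.
#'
#' @param counts A [spot_counts()].
#' @param target_sum Common post-normalization total; `NULL` (default)
#'   uses the median spot total.
#' @param log_transform Apply `log1p` after scaling (default FALSE).
#' @return A `spot_counts` with numeric (non-integer) values.
#' @export
normalize_spots <- function(counts, target_sum = NULL, log_transform = FALSE) {
  stopifnot(inherits(counts, "spot_counts"))
  tot <- Matrix::colSums(counts$counts)
  if (all(tot == 0)) stop("all-zero count matrix", call. = FALSE)
  if (any(tot == 0)) {
    message("dropping ", sum(tot == 0), " zero-total spot(s)")
    keep <- tot > 0
    counts <- spot_counts(counts$counts[, keep, drop = FALSE],
                          counts$spots[keep, , drop = FALSE])
    tot <- tot[keep]
  }
  if (is.null(target_sum)) target_sum <- stats::median(tot)
  m <- counts$counts %*% Matrix::Diagonal(x = target_sum / tot)
  if (log_transform) m@x <- log1p(m@x)
  dimnames(m) <- dimnames(counts$counts)
  out <- counts
  out$counts <- methods::as(m, "CsparseMatrix")
  out
}

#' Stripe-artifact metric: CV of row and column totals
#'
#' Unequal flow in individual channels produces rows or columns of spots
#' with systematically higher or lower counts. The metric is the
#' coefficient of variation of the per-row (and per-column) mean spot
#' totals; 0 indicates no stripe structure. A single row or column is
#' degenerate and reported as 0.
#'
#' @param counts A [spot_counts()] with grid indices in its metadata.
#' @return List with `row_cv` (over `y_idx`) and `col_cv` (over `x_idx`).
#' @export
stripe_metric <- function(counts) {
  stopifnot(inherits(counts, "spot_counts"))
  tot <- Matrix::colSums(counts$counts)
  row_means <- tapply(tot, counts$spots$y_idx, mean)
  col_means <- tapply(tot, counts$spots$x_idx, mean)
  list(row_cv = .cv(as.numeric(row_means)),
       col_cv = .cv(as.numeric(col_means)))
}

#' Sequencing-saturation analysis by read subsampling
#'
#' Subsamples the retained read-level records (pre-UMI-collapse) at a
#' series of fractions, rebuilds the count matrix at each fraction and
#' records the median UMIs and genes per spot. Subsamples are nested (a
#' seeded permutation is drawn once and fraction `f` takes the first
#' `f * n` reads), so curves from one run are directly comparable across
#' fractions. Medians are computed over the spot set of the full run.
#'
#' @param reads Tagged read table as produced by [reads_to_counts()]
#'   (`$reads`): columns `well_id`, `x_idx`, `y_idx`, `umi`, `status`,
#'   `gene`, optionally `region`.
#' @param fractions Subsampling fractions in (0, 1].
#' @param seed RNG seed for the permutation (default 0).
#' @param include_intronic Passed to [digital_expression()].
#' @return Object of class `saturation_curve`: data frame `fraction`,
#'   `median_umis_per_spot`, `median_genes_per_spot`, with the seed as an
#'   attribute.
#' @export
subsample_saturation <- function(reads, fractions = seq(0.1, 1, by = 0.1),
                                 seed = 0L, include_intronic = TRUE) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  a <- data.table::as.data.table(reads)
  n <- nrow(a)
  perm <- .with_seed(seed, sample.int(n))
  full <- digital_expression(a, include_intronic = include_intronic)
  all_spots <- full$spots$spot_id
  rows <- lapply(sort(fractions), function(f) {
    sub <- a[perm[seq_len(floor(f * n))]]
    cm <- digital_expression(sub, include_intronic = include_intronic)
    umis <- stats::setNames(rep(0, length(all_spots)), all_spots)
    genes <- umis
    umis[cm$spots$spot_id] <- cm$spots$total_umis
    genes[cm$spots$spot_id] <- cm$spots$n_genes
    data.frame(fraction = f,
               median_umis_per_spot = stats::median(umis),
               median_genes_per_spot = stats::median(genes))
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' @export
plot.saturation_curve <- function(x, ...) {
  graphics::plot(x$fraction, x$median_umis_per_spot, type = "b", pch = 16,
                 xlab = "subsampling fraction", ylab = "median UMIs / spot",
                 ...)
  invisible(x)
}

#' Fraction of marker genes detected per marker set
#'
#' For each organ/tissue marker set, the fraction of its genes present
#' with nonzero counts in the (filtered) matrix. Gene symbols are
#' compared case-insensitively.
#'
#' @param counts A [spot_counts()], or a character vector of detected
#'   gene identifiers.
#' @param marker_sets Named list of character vectors (set -> genes).
#' @return Named numeric vector of detected fractions.
#' @export
marker_presence <- function(counts, marker_sets) {
  if (inherits(counts, "spot_counts")) {
    present <- rownames(counts$counts)[Matrix::rowSums(counts$counts) > 0]
  } else present <- as.character(counts)
  present <- toupper(present)
  if (any(lengths(marker_sets) == 0L))
    stop("empty marker set", call. = FALSE)
  vapply(marker_sets,
         function(g) mean(toupper(g) %in% present),
         numeric(1))
}

#' Read a marker-set table (two columns: set, gene)
#'
#' @param path TSV file path with columns `set` and `gene`.
#' @return Named list of character vectors.
#' @export
read_marker_sets <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("set", "gene") %in% names(d)))
  split(d$gene, d$set)
}

#' Correlate a pseudobulk profile with bulk expression tables
#'
#' The pseudobulk profile sums the counts of all spots per gene. Both
#' pseudobulk and bulk profiles are scaled to transcripts per million
#' when gene lengths are supplied, otherwise to counts per million
#' (length-free), then `log(1 + x)` transformed; the Pearson correlation
#' is computed pairwise on the shared genes.
#'
#' @param counts A [spot_counts()] or a named numeric vector of gene
#'   totals.
#' @param bulk_table Data frame with a `gene` column plus one numeric
#'   column per bulk sample.
#' @param gene_lengths Optional named vector of gene lengths (bp) for
#'   TPM scaling.
#' @return List with `r` (named correlations per bulk sample), `method`
#'   (`"tpm"` or `"cpm"`) and `n_shared_genes`.
#' @export
pseudobulk_correlate <- function(counts, bulk_table, gene_lengths = NULL) {
  pb <- if (inherits(counts, "spot_counts"))
    Matrix::rowSums(counts$counts) else counts
  stopifnot(!is.null(names(pb)))
  bulk_table <- as.data.frame(bulk_table)
  stopifnot("gene" %in% names(bulk_table))
  shared <- intersect(names(pb), bulk_table$gene)
  if (length(shared) < 2L)
    stop("fewer than 2 shared genes", call. = FALSE)
  method <- if (is.null(gene_lengths)) "cpm" else "tpm"
  to_tpm <- function(v, genes) {
    if (method == "tpm") {
      len <- gene_lengths[genes]
      if (anyNA(len)) stop("missing gene length(s)", call. = FALSE)
      v <- v / len
    }
    v / sum(v) * 1e6
  }
  pbv <- log1p(to_tpm(pb[shared], shared))
  samples <- setdiff(names(bulk_table), "gene")
  r <- vapply(samples, function(s) {
    bv <- bulk_table[[s]][match(shared, bulk_table$gene)]
    stats::cor(pbv, log1p(to_tpm(bv, shared)))
  }, numeric(1))
  list(r = r, method = method, n_shared_genes = length(shared))
}
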