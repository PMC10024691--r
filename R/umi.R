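#' Collapse a set of UMI sequences into molecular clusters
#'
#' Duplicate and near-duplicate UMIs within one (spot, gene) group are
#' merged by single-linkage clustering at Hamming distance <= 1; the
#' number of clusters estimates the number of distinct molecules. The
#' result is independent of the order of the input.
#'
#' @param umis Character vector of equal-length UMI sequences.
#' @return Integer: number of UMI clusters.
#' @examples
#' collapse_umis(c("AAAA", "AAAT", "TTTT"))  # AAAA-AAAT chain + TTTT = 2
#' @export
collapse_umis <- function(umis) {
  u <- unique(umis)
  n <- length(u)
  if (n <= 1L) return(n)
  m <- .seq_mat(u)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    mi <- m[i, ]
    for (j in seq.int(i + 1L, n)) {
      if (sum(mi != m[j, ]) <= 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Spot-by-gene UMI count matrix
#'
#' The central container of the pipeline: a sparse genes x spots matrix
#' of UMI counts plus per-spot metadata (well, grid indices, micrometre
#' coordinates when a spot grid is attached, read/UMI/gene totals, and a
#' tissue flag filled in by [flag_tissue_spots()]).
#'
#' @param counts A matrix or `dgCMatrix`, genes in rows, spots in
#'   columns. Column names must match `spots$spot_id`.
#' @param spots Data frame of per-spot metadata with at least `spot_id`,
#'   `well_id`, `x_idx`, `y_idx`.
#' @return An object of class `spot_counts`.
#' @export
spot_counts <- function(counts, spots) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  spots <- as.data.frame(spots)
  stopifnot(all(c("spot_id", "well_id", "x_idx", "y_idx") %in% names(spots)))
  if (is.null(colnames(counts)) || !identical(colnames(counts), spots$spot_id))
    stop("counts column names must equal spots$spot_id", call. = FALSE)
  if (any(counts@x < 0)) stop("negative counts", call. = FALSE)
  if (!"tissue" %in% names(spots)) spots$tissue <- NA
  structure(list(counts = counts, spots = spots), class = "spot_counts")
}

#' @export
print.spot_counts <- function(x, ...) {
  cat(sprintf("spot_counts: %d genes x %d spots, %s UMIs total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!all(is.na(x$spots$tissue)))
    cat(sprintf("  tissue spots: %d / %d\n",
                sum(x$spots$tissue, na.rm = TRUE), nrow(x$spots)))
  invisible(x)
}

#' @export
dim.spot_counts <- function(x) dim(x$counts)

#' Collapse tagged reads into the digital expression matrix
#'
#' Reads with status `valid` and an assigned gene are grouped by
#' (well, x, y, gene); within each group UMIs are collapsed with
#' [collapse_umis()] and the cluster count becomes the matrix entry.
#' Intronic-region reads are included only when `include_intronic` is
#' `TRUE`.
#'
#' @param assignments Tagged read table: columns `well_id`, `x_idx`,
#'   `y_idx`, `umi`, `status`, `gene`, and optionally `region`.
#' @param grid Optional [build_spot_grid()]; when given, spot micrometre
#'   coordinates are attached and spots are checked against the grid.
#' @param include_intronic Count reads tagged `intronic` (default TRUE)?
#' @return A [spot_counts()] object.
#' @export
digital_expression <- function(assignments, grid = NULL,
                               include_intronic = TRUE) {
  a <- data.table::as.data.table(assignments)
  keep <- a$status == "valid" & !is.na(a$gene)
  if ("region" %in% names(a) && !include_intronic)
    keep <- keep & (is.na(a$region) | a$region != "intronic")
  a <- a[keep]
  if (!"well_id" %in% names(a) || all(is.na(a$well_id)))
    a$well_id <- "W1"

  # per-spot read totals (pre-collapse) and intronic fraction
  x_idx <- y_idx <- well_id <- gene <- umi <- NULL # data.table NSE
  grp <- a[, list(count = collapse_umis(umi), reads = .N),
           by = list(well_id, x_idx, y_idx, gene)]
  spot_key <- sprintf("%s_x%02d_y%02d", grp$well_id, grp$x_idx, grp$y_idx)

  spots <- unique(data.frame(spot_id = spot_key, well_id = grp$well_id,
                             x_idx = grp$x_idx, y_idx = grp$y_idx,
                             stringsAsFactors = FALSE))
  spots <- spots[order(spots$well_id, spots$y_idx, spots$x_idx), , drop = FALSE]
  genes <- sort(unique(grp$gene))
  mat <- Matrix::sparseMatrix(
    i = match(grp$gene, genes),
    j = match(spot_key, spots$spot_id),
    x = grp$count,
    dims = c(length(genes), nrow(spots)),
    dimnames = list(genes, spots$spot_id)
  )
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "spot_grid"))
    m <- match(spots$spot_id, grid$spots$spot_id)
    if (anyNA(m))
      stop("spots not present in the grid: ",
           paste(utils::head(spots$spot_id[is.na(m)]), collapse = ", "),
           call. = FALSE)
    spots$x_um <- grid$spots$x_um[m]
    spots$y_um <- grid$spots$y_um[m]
  }
  tr <- tapply(grp$reads, spot_key, sum)
  spots$total_reads <- as.integer(tr[spots$spot_id])
  spots$total_umis <- Matrix::colSums(mat)
  spots$n_genes <- Matrix::colSums(mat > 0)
  rownames(spots) <- NULL
  spot_counts(mat, spots)
}

#' Summaries of a demultiplexing run
#'
#' Per-spot and per-library RNA metrics: read status tallies, the valid
#' fraction, per-spot UMI/gene totals with medians, the intronic read
#' fraction, and depth-normalized medians per million input reads.
#'
#' @param assignments Tagged read table (see [digital_expression()]).
#' @param counts The matching [spot_counts()].
#' @param total_reads Sequencing depth used for per-million scaling;
#'   defaults to `nrow(assignments)`.
#' @return List with `n_reads`, `status_counts`, `valid_fraction`,
#'   `intronic_fraction`, `per_spot` (data frame), `median_umis_per_spot`,
#'   `median_genes_per_spot` and their `*_per_1e6` depth-normalized
#'   versions.
#' @export
rna_metrics <- function(assignments, counts, total_reads = NULL) {
  a <- data.table::as.data.table(assignments)
  if (is.null(total_reads)) total_reads <- nrow(a)
  st <- table(a$status)
  valid <- a$status == "valid"
  intr <- if ("region" %in% names(a))
    mean(a$region[valid & !is.na(a$gene)] == "intronic", na.rm = TRUE)
  else NA_real_
  per_spot <- counts$spots[, c("spot_id", "total_reads", "total_umis", "n_genes")]
  med_umis <- stats::median(per_spot$total_umis)
  med_genes <- stats::median(per_spot$n_genes)
  list(
    n_reads = nrow(a),
    status_counts = as.list(st),
    valid_fraction = unname(sum(valid) / nrow(a)),
    intronic_fraction = intr,
    per_spot = per_spot,
    median_umis_per_spot = med_umis,
    median_genes_per_spot = med_genes,
    median_umis_per_spot_per_1e6 = med_umis / total_reads * 1e6,
    median_genes_per_spot_per_1e6 = med_genes / total_reads * 1e6
  )
}

#' Write or read a spot count matrix as MatrixMarket + TSV sidecars
#'
#' Writes `<prefix>.mtx` (genes x spots sparse counts),
#' `<prefix>.genes.tsv` and `<prefix>.spots.tsv`.
#'
#' @param x A [spot_counts()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_spot_counts <- function(x, prefix) {
  stopifnot(inherits(x, "spot_counts"))
  Matrix::writeMM(x$counts, paste0(prefix, ".mtx"))
  utils::write.table(data.frame(gene = rownames(x$counts)),
                     paste0(prefix, ".genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$spots, paste0(prefix, ".spots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_spot_counts
#' @export
read_spot_counts <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  genes <- utils::read.delim(paste0(prefix, ".genes.tsv"))$gene
  spots <- utils::read.delim(paste0(prefix, ".spots.tsv"),
                             stringsAsFactors = FALSE)
  dimnames(m) <- list(genes, spots$spot_id)
  spot_counts(m, spots)
}
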