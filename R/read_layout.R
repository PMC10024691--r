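#' Describe the structure of read 2
#'
#' Read 2 of a deterministic-barcoding library carries the UMI and the
#' spatial/well barcodes as fixed-position segments. A read layout is an
#' ordered table of segments, each with a role, a 0-based start offset and
#' a length in nucleotides. Exactly one segment per barcode role is
#' allowed; the well (z) barcode is optional. `linker` and `ignore`
#' segments are skipped during extraction.
#'
#' @param segments Data frame with columns `role`
#'   (`umi`, `x_barcode`, `y_barcode`, `z_barcode`, `linker`, `ignore`),
#'   `start` (0-based) and `length` (nt).
#' @return An object of class `read_layout`.
#' @seealso [default_read_layout()] for the standard segment order.
#' @export
read_layout <- function(segments) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("role", "start", "length") %in% names(segments)))
  roles <- c("umi", "x_barcode", "y_barcode", "z_barcode", "linker", "ignore")
  if (!all(segments$role %in% roles))
    stop("unknown segment role(s): ",
         paste(setdiff(segments$role, roles), collapse = ", "), call. = FALSE)
  segments$start <- as.integer(segments$start)
  segments$length <- as.integer(segments$length)
  if (any(segments$start < 0L) || any(segments$length < 1L))
    stop("segments need start >= 0 and length >= 1", call. = FALSE)
  for (r in c("umi", "x_barcode", "y_barcode", "z_barcode")) {
    k <- sum(segments$role == r)
    if (r == "z_barcode") {
      if (k > 1L) stop("at most one z_barcode segment allowed", call. = FALSE)
    } else if (k != 1L) {
      stop("exactly one ", r, " segment required", call. = FALSE)
    }
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  ends <- segments$start + segments$length
  if (any(segments$start[-1L] < ends[-length(ends)]))
    stop("read segments overlap", call. = FALSE)
  rownames(segments) <- NULL
  structure(list(segments = segments, min_read_length = max(ends)),
            class = "read_layout")
}

#' Standard read 2 layout: UMI - x - linker - y - linker - z
#'
#' @param umi_len UMI length in nt (default 10).
#' @param barcode_len Spatial/well barcode length in nt (default 8).
#' @param linker_len Length of the ligation linker between barcodes
#'   (default 20).
#' @param with_z Include the well (z) barcode segment? Use `FALSE` for
#'   libraries multiplexed only by library index.
#' @return A [read_layout()].
#' @export
default_read_layout <- function(umi_len = 10L, barcode_len = 8L,
                                linker_len = 20L, with_z = TRUE) {
  segs <- list(
    list(role = "umi", length = umi_len),
    list(role = "x_barcode", length = barcode_len),
    list(role = "linker", length = linker_len),
    list(role = "y_barcode", length = barcode_len)
  )
  if (with_z) {
    segs <- c(segs, list(list(role = "linker", length = linker_len),
                         list(role = "z_barcode", length = barcode_len)))
  }
  start <- 0L
  rows <- lapply(segs, function(s) {
    r <- data.frame(role = s$role, start = start, length = s$length)
    start <<- start + as.integer(s$length)
    r
  })
  read_layout(do.call(rbind, rows))
}

#' @export
print.read_layout <- function(x, ...) {
  cat("read_layout (read 2), segments:\n")
  print(x$segments, row.names = FALSE)
  cat(sprintf("minimum read length: %d nt\n", x$min_read_length))
  invisible(x)
}

.layout_segment <- function(layout, role) {
  s <- layout$segments[layout$segments$role == role, , drop = FALSE]
  if (nrow(s) == 0L) NULL else s
}

.layout_has_z <- function(layout) !is.null(.layout_segment(layout, "z_barcode"))

#' Barcode legend: which sequence encodes which channel or well
#'
#' For the spatial axes (`x`, `y`) the legend maps each barcode sequence
#' to a 0-based channel index; for the well axis (`z`) it maps sequences
#' to well identifiers, and several sequences may map to the same well
#' (reverse-transcription primer sets typically carry 4 barcodes per
#' well).
#'
#' @param x,y Named integer vectors: `names` are barcode sequences,
#'   values are channel indices.
#' @param z Optional named character vector: `names` are barcode
#'   sequences, values are well identifiers.
#' @return An object of class `barcode_legend` with elements `x`, `y`,
#'   `z` (each a data frame `sequence`, `index` or `well`).
#' @export
barcode_legend <- function(x, y, z = NULL) {
  ax <- function(v, value_col, coerce) {
    seqs <- toupper(names(v))
    if (is.null(seqs) || any(!nzchar(seqs)))
      stop("legend vectors must be named by barcode sequence", call. = FALSE)
    if (anyDuplicated(seqs))
      stop("duplicate barcode sequence within an axis", call. = FALSE)
    if (!all(.is_dna(seqs)))
      stop("barcode sequences must be uppercase ACGT", call. = FALSE)
    if (length(unique(nchar(seqs))) != 1L)
      stop("barcodes within an axis must share one length", call. = FALSE)
    d <- data.frame(sequence = seqs, v = coerce(unname(v)),
                    stringsAsFactors = FALSE)
    names(d)[2] <- value_col
    d
  }
  out <- list(x = ax(x, "index", as.integer), y = ax(y, "index", as.integer))
  if (!is.null(z)) out$z <- ax(z, "well", as.character)
  structure(out, class = "barcode_legend")
}

#' @export
print.barcode_legend <- function(x, ...) {
  cat(sprintf("barcode_legend: %d x-, %d y-barcodes", nrow(x$x), nrow(x$y)))
  if (!is.null(x$z))
    cat(sprintf(", %d z-barcodes over %d wells",
                nrow(x$z), length(unique(x$z$well))))
  cat("\n")
  invisible(x)
}

#' Read or write a barcode legend CSV
#'
#' The file has columns `axis` (`x`, `y` or `z`), `sequence` and
#' `index_or_well` (channel index for x/y, well identifier for z).
#'
#' @param path File path.
#' @return `read_barcode_legend` returns a [barcode_legend()].
#' @export
read_barcode_legend <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("axis", "sequence", "index_or_well") %in% names(d)))
  pick <- function(a) d[d$axis == a, , drop = FALSE]
  xv <- stats::setNames(as.integer(pick("x")$index_or_well), pick("x")$sequence)
  yv <- stats::setNames(as.integer(pick("y")$index_or_well), pick("y")$sequence)
  zt <- pick("z")
  zv <- if (nrow(zt)) stats::setNames(as.character(zt$index_or_well), zt$sequence)
  barcode_legend(xv, yv, zv)
}

#' @rdname read_barcode_legend
#' @param legend A [barcode_legend()].
#' @export
write_barcode_legend <- function(legend, path) {
  stopifnot(inherits(legend, "barcode_legend"))
  rows <- rbind(
    data.frame(axis = "x", sequence = legend$x$sequence,
               index_or_well = as.character(legend$x$index)),
    data.frame(axis = "y", sequence = legend$y$sequence,
               index_or_well = as.character(legend$y$index))
  )
  if (!is.null(legend$z))
    rows <- rbind(rows, data.frame(axis = "z", sequence = legend$z$sequence,
                                   index_or_well = legend$z$well))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
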