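#' Describe a deterministic-barcoding chip layout
#'
#' A chip consists of `n_channels` parallel microchannels per axis, each
#' `channel_width` micrometres wide and spaced `pitch` micrometres
#' centre-to-centre. Channel intersections define the spatial spots. The
#' outermost channels are typically filled with a fluorescent alignment
#' marker instead of barcodes; their indices are given in
#' `alignment_channels`. The serpentine channel routing addresses
#' `grid_rows * grid_cols` capture areas (tissue wells) in parallel.
#'
#' Defaults describe the 38-channel chip with 50 um channels at 100 um
#' pitch, alignment markers in channels 0 and 37, and a 3 x 3 arrangement
#' of capture areas.
#'
#' @param n_channels Number of channels per axis (same in x and y).
#' @param channel_width Channel width in micrometres.
#' @param pitch Centre-to-centre channel distance in micrometres.
#' @param alignment_channels 0-based indices of channels carrying the
#'   alignment marker (no spatial barcode). May be empty.
#' @param grid_rows,grid_cols Arrangement of capture areas on the slide.
#' @param section_origins Optional data frame with columns `well_id`,
#'   `x0`, `y0` giving the top-left origin of each capture area in
#'   micrometres. By default areas are tiled at a spacing of
#'   `n_channels * pitch` and named `A1`, `A2`, ... row-major.
#' @param round1_axis Which spot index the first ligation round (the
#'   horizontally routed channels) encodes: `"y"` (default, rows) or
#'   `"x"`. The mapping is a convention switch; all geometry is symmetric
#'   in the two axes.
#' @return An object of class `chip_layout`.
#' @examples
#' layout <- chip_layout()
#' layout
#' compute_scan_area(layout)
#' @export
chip_layout <- function(n_channels = 38L,
                        channel_width = 50,
                        pitch = 100,
                        alignment_channels = c(0L, n_channels - 1L),
                        grid_rows = 3L,
                        grid_cols = 3L,
                        section_origins = NULL,
                        round1_axis = c("y", "x")) {
  round1_axis <- match.arg(round1_axis)
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("n_channels must be >= 1", call. = FALSE)
  if (channel_width <= 0 || pitch <= 0 || channel_width > pitch)
    stop("need 0 < channel_width <= pitch", call. = FALSE)
  alignment_channels <- as.integer(alignment_channels)
  alignment_channels <- sort(unique(alignment_channels))
  if (length(alignment_channels) &&
      (min(alignment_channels) < 0L || max(alignment_channels) >= n_channels))
    stop("alignment channel index out of range [0, n_channels)", call. = FALSE)
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  if (grid_rows < 1L || grid_cols < 1L)
    stop("capture-area grid must be at least 1 x 1", call. = FALSE)

  if (is.null(section_origins)) {
    spacing <- n_channels * pitch
    idx <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows))
    section_origins <- data.frame(
      well_id = paste0(LETTERS[idx$row], idx$col),
      x0 = (idx$col - 1L) * spacing,
      y0 = (idx$row - 1L) * spacing,
      stringsAsFactors = FALSE
    )
  } else {
    section_origins <- as.data.frame(section_origins)
    stopifnot(all(c("well_id", "x0", "y0") %in% names(section_origins)))
    if (nrow(section_origins) != grid_rows * grid_cols)
      stop("section_origins must have one row per capture area", call. = FALSE)
    if (anyDuplicated(section_origins$well_id))
      stop("duplicate well_id in section_origins", call. = FALSE)
  }

  structure(
    list(
      n_channels = n_channels,
      channel_width = channel_width,
      pitch = pitch,
      alignment_channels = alignment_channels,
      grid_rows = grid_rows,
      grid_cols = grid_cols,
      section_origins = section_origins,
      round1_axis = round1_axis
    ),
    class = "chip_layout"
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf(
    "chip_layout: %d channels/axis, %g um wide, %g um pitch\n",
    x$n_channels, x$channel_width, x$pitch))
  cat(sprintf("  alignment channels: %s\n",
              if (length(x$alignment_channels))
                paste(x$alignment_channels, collapse = ", ") else "none"))
  cat(sprintf("  capture areas: %d x %d (%s)\n", x$grid_rows, x$grid_cols,
              paste(utils::head(x$section_origins$well_id, 4), collapse = ", ")))
  cat(sprintf("  barcoded spots per area: %d^2 = %d\n",
              n_barcoded_channels(x), n_barcoded_channels(x)^2))
  invisible(x)
}

#' Channel indices that carry spatial barcodes
#'
#' @param layout A [chip_layout()].
#' @return Integer vector of 0-based channel indices excluding alignment
#'   channels.
#' @export
barcoded_channels <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  setdiff(seq_len(layout$n_channels) - 1L, layout$alignment_channels)
}

#' @rdname barcoded_channels
#' @export
n_barcoded_channels <- function(layout) length(barcoded_channels(layout))

#' Centre of a spot in slide micrometre coordinates
#'
#' The centre of the intersection of channel `x_idx` (vertical, column)
#' and `y_idx` (horizontal, row): the capture-area origin plus
#' `idx * pitch + channel_width / 2` on each axis.
#'
#' @param layout A [chip_layout()].
#' @param well_id Capture-area identifier (must appear in
#'   `layout$section_origins`).
#' @param x_idx,y_idx 0-based channel indices.
#' @return Numeric vector `c(x, y)` in micrometres.
#' @export
spot_center <- function(layout, well_id, x_idx, y_idx) {
  stopifnot(inherits(layout, "chip_layout"))
  i <- match(well_id, layout$section_origins$well_id)
  if (any(is.na(i))) stop("unknown well_id: ",
                          paste(well_id[is.na(i)], collapse = ", "), call. = FALSE)
  if (any(x_idx < 0 | x_idx >= layout$n_channels) ||
      any(y_idx < 0 | y_idx >= layout$n_channels))
    stop("channel index out of range", call. = FALSE)
  half <- layout$channel_width / 2
  cbind(x = layout$section_origins$x0[i] + x_idx * layout$pitch + half,
        y = layout$section_origins$y0[i] + y_idx * layout$pitch + half)
}

#' Enumerate every spot of a chip layout
#'
#' Builds the full spot array: one spot per channel intersection per
#' capture area, in deterministic order (capture area, then row `y_idx`,
#' then column `x_idx`). Spots on alignment channels are included with
#' `is_barcoded = FALSE` so that both the raw intersection count and the
#' barcoded-spot count are represented.
#'
#' @param layout A [chip_layout()].
#' @return An object of class `spot_grid`: a list with elements `layout`
#'   and `spots` (a data frame with columns `spot_id`, `well_id`, `x_idx`,
#'   `y_idx`, `x_um`, `y_um`, `is_barcoded`).
#' @examples
#' g <- build_spot_grid(chip_layout(grid_rows = 1, grid_cols = 1))
#' nrow(g$spots)           # 38 * 38 = 1444 intersections
#' sum(g$spots$is_barcoded) # 36 * 36 = 1296 barcoded spots
#' @export
build_spot_grid <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  n <- layout$n_channels
  per_area <- expand.grid(x_idx = seq_len(n) - 1L, y_idx = seq_len(n) - 1L)
  per_area <- per_area[order(per_area$y_idx, per_area$x_idx), , drop = FALSE]
  half <- layout$channel_width / 2
  pieces <- lapply(seq_len(nrow(layout$section_origins)), function(i) {
    o <- layout$section_origins[i, ]
    data.frame(
      well_id = o$well_id,
      x_idx = per_area$x_idx,
      y_idx = per_area$y_idx,
      x_um = o$x0 + per_area$x_idx * layout$pitch + half,
      y_um = o$y0 + per_area$y_idx * layout$pitch + half,
      is_barcoded = !(per_area$x_idx %in% layout$alignment_channels |
                        per_area$y_idx %in% layout$alignment_channels),
      stringsAsFactors = FALSE
    )
  })
  spots <- do.call(rbind, pieces)
  spots$spot_id <- sprintf("%s_x%02d_y%02d", spots$well_id, spots$x_idx, spots$y_idx)
  rownames(spots) <- NULL
  spots <- spots[, c("spot_id", "well_id", "x_idx", "y_idx", "x_um", "y_um",
                     "is_barcoded")]
  structure(list(layout = layout, spots = spots), class = "spot_grid")
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("spot_grid: %d spots (%d barcoded) over %d capture area(s)\n",
              nrow(x$spots), sum(x$spots$is_barcoded),
              nrow(x$layout$section_origins)))
  invisible(x)
}

#' Total imaged scan area of a chip design
#'
#' Each capture area spans a square of side
#' `n_barcoded_channels * pitch`; the scan area is that square times the
#' number of capture areas, in mm^2. The fold change is reported against a
#' reference design (default: the 25 mm^2 single-section chip).
#'
#' @param layout A [chip_layout()].
#' @param reference_area_mm2 Reference scan area for the fold change.
#' @return List with `area_mm2`, `fold_change` and `n_capture_areas`.
#' @examples
#' compute_scan_area(chip_layout())  # 116.64 mm^2, 4.66-fold over 25 mm^2
#' @export
compute_scan_area <- function(layout, reference_area_mm2 = 25) {
  stopifnot(inherits(layout, "chip_layout"))
  n_areas <- layout$grid_rows * layout$grid_cols
  side_um <- n_barcoded_channels(layout) * layout$pitch
  area_mm2 <- n_areas * (side_um / 1000)^2
  list(area_mm2 = area_mm2,
       fold_change = area_mm2 / reference_area_mm2,
       n_capture_areas = n_areas)
}

#' Write a spot grid as a tab-separated table
#'
#' @param grid A [build_spot_grid()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spot_grid <- function(grid, path) {
  stopifnot(inherits(grid, "spot_grid"))
  utils::write.table(grid$spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a chip layout configuration file
#'
#' Layout configurations are stored as YAML key-value files with the same
#' field names as [chip_layout()]; `section_origins` is a list of
#' `{well_id, x0, y0}` records.
#'
#' @param path File path.
#' @return `read_chip_layout` returns a [chip_layout()].
#' @export
read_chip_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  so <- NULL
  if (!is.null(cfg$section_origins))
    so <- do.call(rbind, lapply(cfg$section_origins, as.data.frame))
  chip_layout(
    n_channels = cfg$n_channels %||% 38L,
    channel_width = cfg$channel_width %||% 50,
    pitch = cfg$pitch %||% 100,
    alignment_channels = cfg$alignment_channels %||% integer(0),
    grid_rows = cfg$grid_rows %||% 1L,
    grid_cols = cfg$grid_cols %||% 1L,
    section_origins = so,
    round1_axis = cfg$round1_axis %||% "y"
  )
}

#' @rdname read_chip_layout
#' @param layout A [chip_layout()].
#' @export
write_chip_layout <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  cfg <- layout[c("n_channels", "channel_width", "pitch",
                  "alignment_channels", "grid_rows", "grid_cols", "round1_axis")]
  cfg$section_origins <- lapply(seq_len(nrow(layout$section_origins)), function(i)
    as.list(layout$section_origins[i, ]))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
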