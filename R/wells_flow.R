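#' Quantify well cross-contamination from well-barcode composition
#'
#' When samples carry both a library index and a reverse-transcription
#' well barcode, reads sequenced in library L but carrying another
#' well's barcode measure cross-contamination. Reads are aggregated by
#' (library, resolved well) and converted to row percentages; a well's
#' contamination is 100 minus its own-barcode percentage. Reads dropped
#' as `crosstalk` by the demultiplexer are counted here (the composition
#' is computed before any dropping).
#'
#' @param assignments Assignment table with columns `library`,
#'   `well_id` and `status` (statuses `valid` and `crosstalk` carry a
#'   resolved well barcode).
#' @return Object of class `well_composition`: `percent` (matrix
#'   libraries x wells, rows summing to 100), `counts`, `own` and
#'   `contamination` (named vectors, percent).
#' @export
well_composition <- function(assignments) {
  a <- data.table::as.data.table(assignments)
  stopifnot(all(c("library", "well_id", "status") %in% names(a)))
  a <- a[a$status %in% c("valid", "crosstalk") & !is.na(a$well_id)]
  if (nrow(a) == 0L)
    stop("no reads with a resolved well barcode", call. = FALSE)
  tab <- table(a$library, a$well_id)
  if (any(rowSums(tab) == 0L))
    stop("library without resolved well barcodes", call. = FALSE)
  pct <- sweep(unclass(tab), 1L, rowSums(tab), "/") * 100
  libs <- rownames(pct)
  own <- vapply(libs, function(l)
    if (l %in% colnames(pct)) pct[l, l] else 0, numeric(1))
  structure(list(percent = pct, counts = unclass(tab),
                 own = own, contamination = 100 - own),
            class = "well_composition")
}

#' @export
print.well_composition <- function(x, ...) {
  cat("well_composition (% of reads per well barcode):\n")
  print(round(x$percent, 2))
  cat(sprintf("mean contamination: %.2f%%\n", mean(x$contamination)))
  invisible(x)
}

#' Long-format table of a well composition (stacked-bar ready)
#'
#' @param x A [well_composition()].
#' @return Data frame `library`, `well_barcode`, `percent`.
#' @export
composition_long <- function(x) {
  stopifnot(inherits(x, "well_composition"))
  d <- as.data.frame(as.table(x$percent), stringsAsFactors = FALSE)
  names(d) <- c("library", "well_barcode", "percent")
  d
}

#' Fit the flow-rate vs channel-length regression
#'
#' Ordinary least squares fit of volumetric flow rate (uL/min) against
#' microchannel length (mm). At fixed driving pressure the
#' Hagen-Poiseuille relation predicts flow inversely related to length,
#' which over a narrow length range appears as a negative linear trend.
#'
#' @param lengths Channel lengths in mm, or a data frame with columns
#'   `length_mm` and `flow_ul_min`.
#' @param flow_rates Flow rates in uL/min (omit when `lengths` is a data
#'   frame).
#' @return Object of class `flow_model` wrapping the `lm` fit, with
#'   `slope` (uL/min per mm), `intercept` (uL/min), Pearson `r`,
#'   `p_value` and the fitted `length_range`. Constant response yields
#'   `r = 0` with a warning.
#' @examples
#' fm <- fit_flow_regression(c(100, 150, 200), 10 - 0.02 * c(100, 150, 200))
#' coef(fm)
#' @export
fit_flow_regression <- function(lengths, flow_rates = NULL) {
  if (is.data.frame(lengths)) {
    stopifnot(all(c("length_mm", "flow_ul_min") %in% names(lengths)))
    flow_rates <- lengths$flow_ul_min
    lengths <- lengths$length_mm
  }
  if (length(lengths) < 3L || length(unique(lengths)) < 2L)
    stop("need >= 3 measurements over >= 2 distinct lengths", call. = FALSE)
  d <- data.frame(length_mm = lengths, flow_ul_min = flow_rates)
  fit <- stats::lm(flow_ul_min ~ length_mm, data = d)
  if (stats::sd(flow_rates) == 0) {
    warning("constant flow rates; correlation undefined, reported as 0")
    r <- 0; p <- NA_real_
  } else {
    ct <- stats::cor.test(lengths, flow_rates)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(fit = fit,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, p_value = p,
                 length_range = range(lengths),
                 data = d),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf(
    "flow_model: flow = %.4g %+.4g * length  (uL/min, length in mm)\n",
    x$intercept, x$slope))
  cat(sprintf("  Pearson r = %.3f, p = %.3g, fitted over %.1f-%.1f mm\n",
              x$r, x$p_value, x$length_range[1], x$length_range[2]))
  invisible(x)
}

#' @export
summary.flow_model <- function(object, ...) summary(object$fit, ...)

#' @export
coef.flow_model <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.flow_model <- function(object, ...) stats::residuals(object$fit)

#' Predict flow rates with confidence or prediction intervals
#'
#' @param object A [fit_flow_regression()] model.
#' @param newdata Numeric lengths (mm) or data frame with `length_mm`.
#' @param interval `"confidence"` (mean response, default),
#'   `"prediction"` (new observations) or `"none"`.
#' @param level Interval level (default 0.95).
#' @param ... Unused.
#' @return Data frame with `fit`, and `lwr`/`upr` unless
#'   `interval = "none"`.
#' @export
predict.flow_model <- function(object, newdata = NULL,
                               interval = c("confidence", "prediction", "none"),
                               level = 0.95, ...) {
  interval <- match.arg(interval)
  if (is.null(newdata)) newdata <- object$data
  if (!is.data.frame(newdata)) newdata <- data.frame(length_mm = newdata)
  p <- stats::predict(object$fit, newdata = newdata,
                      interval = if (interval == "none") "none" else interval,
                      level = level)
  if (interval == "none") data.frame(fit = as.numeric(p)) else as.data.frame(p)
}

#' @export
plot.flow_model <- function(x, level = 0.95, ...) {
  d <- x$data
  grid <- data.frame(length_mm = seq(min(d$length_mm), max(d$length_mm),
                                     length.out = 100))
  cf <- predict(x, grid, interval = "confidence", level = level)
  pf <- predict(x, grid, interval = "prediction", level = level)
  graphics::plot(d$length_mm, d$flow_ul_min, pch = 16,
                 xlab = "channel length (mm)", ylab = "flow rate (uL/min)",
                 ylim = range(pf, d$flow_ul_min), ...)
  graphics::lines(grid$length_mm, cf$fit)
  graphics::lines(grid$length_mm, cf$lwr, lty = 2, col = "blue")
  graphics::lines(grid$length_mm, cf$upr, lty = 2, col = "blue")
  graphics::lines(grid$length_mm, pf$lwr, lty = 3, col = "red")
  graphics::lines(grid$length_mm, pf$upr, lty = 3, col = "red")
  invisible(x)
}

#' Simulate flow-rate measurements from a fitted model
#'
#' @param object A [fit_flow_regression()] model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return As [stats::simulate()] for `lm`.
#' @export
simulate.flow_model <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed)
}

#' Longest channel operable at a minimum flow rate
#'
#' Inverts the fitted line: the length at which the predicted mean flow
#' falls to `min_flow`. The conservative variant instead finds where the
#' lower bound of the prediction interval crosses `min_flow`, and is
#' never longer than the point estimate.
#'
#' @param model A [fit_flow_regression()] result (negative slope
#'   required).
#' @param min_flow Minimal acceptable flow rate in uL/min.
#' @param conservative Use the prediction-interval lower bound?
#' @param level Prediction-interval level (default 0.95).
#' @return Length in mm.
#' @export
max_operable_length <- function(model, min_flow, conservative = FALSE,
                                level = 0.95) {
  stopifnot(inherits(model, "flow_model"))
  if (model$slope >= -1e-12)
    stop("non-negative slope: flow does not decrease with length",
         call. = FALSE)
  point <- (min_flow - model$intercept) / model$slope
  if (!conservative) return(point)
  f <- function(L) predict(model, L, interval = "prediction",
                           level = level)$lwr - min_flow
  if (f(0) <= 0) return(0)
  stats::uniroot(f, c(0, point))$root
}

#' Ideal laminar flow through a rectangular microchannel
#'
#' First-order rectangular-duct approximation of the Hagen-Poiseuille
#' relation: `Q = (w * h^3 * dP) / (12 * mu * L) * (1 - 0.63 * h / w)`
#' with `h <= w` (dimensions are swapped otherwise). Flow is
#' proportional to the pressure drop and inversely proportional to the
#' channel length.
#'
#' @param length_mm Channel length in mm.
#' @param pressure_drop_mbar Driving pressure in mbar.
#' @param width_um,height_um Channel cross-section in micrometres
#'   (defaults 50 x 50).
#' @param viscosity_pa_s Dynamic viscosity in Pa s (default 1e-3,
#'   water at 20 C).
#' @return Volumetric flow rate in uL/min.
#' @export
hagen_poiseuille_flow <- function(length_mm, pressure_drop_mbar,
                                  width_um = 50, height_um = 50,
                                  viscosity_pa_s = 1e-3) {
  if (any(length_mm <= 0) || any(pressure_drop_mbar <= 0) ||
      any(width_um <= 0) || any(height_um <= 0) || viscosity_pa_s <= 0)
    stop("all physical inputs must be positive", call. = FALSE)
  w <- pmax(width_um, height_um) * 1e-6
  h <- pmin(width_um, height_um) * 1e-6
  L <- length_mm * 1e-3
  dP <- pressure_drop_mbar * 100            # mbar -> Pa
  Q <- (w * h^3 * dP) / (12 * viscosity_pa_s * L) * (1 - 0.63 * h / w)
  Q * 1e9 * 60                              # m^3/s -> uL/min
}

#' Check the washing-volume requirement per channel
#'
#' Washing must exchange a minimal volume in every channel; the slowest
#' channel governs the required wash time.
#'
#' @param flow_rates Per-channel flow rates in uL/min (named or not), or
#'   a [fit_flow_regression()] model together with `lengths`.
#' @param wash_time_s Wash duration in seconds.
#' @param min_volume_ul Required exchanged volume (default 15 uL).
#' @param lengths Channel lengths (mm) when `flow_rates` is a model.
#' @return List with `volume_ul` per channel, `pass` (logical),
#'   `all_pass`, and `required_time_s` (time for the slowest channel to
#'   reach the requirement).
#' @export
wash_volume_check <- function(flow_rates, wash_time_s, min_volume_ul = 15,
                              lengths = NULL) {
  if (inherits(flow_rates, "flow_model")) {
    stopifnot(!is.null(lengths))
    flow_rates <- predict(flow_rates, lengths, interval = "none")$fit
  }
  vol <- flow_rates * wash_time_s / 60
  list(volume_ul = vol,
       pass = vol >= min_volume_ul,
       all_pass = all(vol >= min_volume_ul),
       required_time_s = min_volume_ul / min(flow_rates) * 60)
}

#' Read flow measurements from a TSV file
#'
#' @param path TSV with columns `channel_id`, `length_mm`,
#'   `flow_ul_min`.
#' @return Data frame.
#' @export
read_flow_measurements <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("channel_id", "length_mm", "flow_ul_min") %in% names(d)))
  d
}
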