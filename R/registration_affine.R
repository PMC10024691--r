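#' Planar affine transforms
#'
#' An affine transform is stored as a 2 x 3 coefficient matrix `M` so
#' that a source point `(x, y)` maps to `M %*% c(x, y, 1)`. Image
#' coordinates follow the raster convention: x = column (rightward),
#' y = row (downward), origin at the top-left.
#'
#' @param m Numeric 2 x 3 matrix.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(m) {
  m <- matrix(as.numeric(m), 2L, 3L)
  if (abs(det(m[, 1:2])) < .Machine$double.eps)
    stop("linear part of the affine transform is singular", call. = FALSE)
  structure(m, class = c("affine2d", "matrix"))
}

#' @rdname affine2d
#' @export
affine_identity <- function() affine2d(cbind(diag(2), c(0, 0)))

#' @rdname affine2d
#' @param tx,ty Translation components.
#' @export
affine_translation <- function(tx, ty) affine2d(cbind(diag(2), c(tx, ty)))

#' @rdname affine2d
#' @param scale Isotropic scale factor.
#' @param angle_deg Rotation angle in degrees (positive = from +x toward
#'   +y, i.e. clockwise on a y-down raster).
#' @export
affine_similarity <- function(scale = 1, angle_deg = 0, tx = 0, ty = 0) {
  a <- angle_deg * pi / 180
  affine2d(cbind(scale * matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L),
                 c(tx, ty)))
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d (2x3):\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param tf An [affine2d()].
#' @param pts N x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return N x 2 matrix of transformed coordinates.
#' @export
apply_affine <- function(tf, pts) {
  stopifnot(inherits(tf, "affine2d"))
  pts <- matrix(as.numeric(pts), ncol = 2L)
  if (nrow(pts) == 0L)
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  out <- pts %*% t(unclass(tf)[, 1:2]) +
    matrix(unclass(tf)[, 3], nrow(pts), 2L, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

#' Compose and invert affine transforms
#'
#' `compose_affine(outer, inner)` returns the transform equivalent to
#' applying `inner` first, then `outer`.
#'
#' @param outer,inner,tf [affine2d()] objects.
#' @return An [affine2d()].
#' @export
compose_affine <- function(outer, inner) {
  A <- unclass(outer)[, 1:2]; a <- unclass(outer)[, 3]
  B <- unclass(inner)[, 1:2]; b <- unclass(inner)[, 3]
  affine2d(cbind(A %*% B, A %*% b + a))
}

#' @rdname compose_affine
#' @export
invert_affine <- function(tf) {
  A <- unclass(tf)[, 1:2]; a <- unclass(tf)[, 3]
  Ai <- solve(A)
  affine2d(cbind(Ai, -Ai %*% a))
}

#' Least-squares affine estimation from point correspondences
#'
#' Finds the affine transform minimizing the summed squared distance
#' between transformed source points and destination points. With three
#' non-collinear correspondences the fit is exact.
#'
#' @param src,dst N x 2 matrices of corresponding (x, y) points, N >= 3.
#' @return An [affine2d()] with attribute `rms_residual`.
#' @export
estimate_affine <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2L)
  dst <- matrix(as.numeric(dst), ncol = 2L)
  if (nrow(src) != nrow(dst) || nrow(src) < 3L)
    stop("need >= 3 point correspondences", call. = FALSE)
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L)
    stop("source points are collinear; affine transform is underdetermined",
         call. = FALSE)
  coefs <- qr.solve(X, dst)           # 3 x 2
  tf <- affine2d(t(coefs))
  res <- apply_affine(tf, src) - dst
  attr(tf, "rms_residual") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Transform a transform to/from JSON
#'
#' @param tf An [affine2d()].
#' @param path JSON file path.
#' @export
write_affine_json <- function(tf, path) {
  stopifnot(inherits(tf, "affine2d"))
  jsonlite::write_json(list(matrix = unclass(tf)), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  affine2d(jsonlite::fromJSON(path)$matrix)
}

#' Project grid spots into image pixel coordinates
#'
#' Applies a micrometre-to-pixel affine transform to every spot centre
#' and to the four corners of each spot's square capture outline
#' (side = channel width). Spots landing outside the image bounds are
#' flagged, not dropped.
#'
#' @param grid A [build_spot_grid()].
#' @param tf [affine2d()] mapping micrometre coordinates to pixels.
#' @param image_dim Optional `c(width, height)` in pixels used to set the
#'   `in_bounds` flag.
#' @return List with `centers` (data frame `spot_id`, `px_x`, `px_y`,
#'   `in_bounds`) and `corners` (data frame `spot_id`, `corner`, `px_x`,
#'   `px_y`; corners ordered TL, TR, BR, BL in the source frame).
#' @export
project_spots <- function(grid, tf, image_dim = NULL) {
  stopifnot(inherits(grid, "spot_grid"), inherits(tf, "affine2d"))
  s <- grid$spots
  ctr <- apply_affine(tf, cbind(s$x_um, s$y_um))
  half <- grid$layout$channel_width / 2
  dx <- c(-half, half, half, -half)
  dy <- c(-half, -half, half, half)
  corner_src <- cbind(rep(s$x_um, each = 4L) + rep(dx, nrow(s)),
                      rep(s$y_um, each = 4L) + rep(dy, nrow(s)))
  corner_px <- apply_affine(tf, corner_src)
  in_bounds <- if (is.null(image_dim)) rep(NA, nrow(s)) else
    ctr[, 1] >= 0 & ctr[, 1] <= image_dim[1] &
    ctr[, 2] >= 0 & ctr[, 2] <= image_dim[2]
  list(
    centers = data.frame(spot_id = s$spot_id, px_x = ctr[, 1],
                         px_y = ctr[, 2], in_bounds = in_bounds,
                         stringsAsFactors = FALSE),
    corners = data.frame(spot_id = rep(s$spot_id, each = 4L),
                         corner = rep(1:4, nrow(s)),
                         px_x = corner_px[, 1], px_y = corner_px[, 2],
                         stringsAsFactors = FALSE)
  )
}
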