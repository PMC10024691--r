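# Image-based registration: fiducial-frame corner detection and
# feature-based matching between imaging rounds.
#
# Image convention throughout: a numeric matrix whose first index is x
# (column, rightward) and second index is y (row, downward), matching
# EBImage. Pixel (i, j) covers the continuous square
# [i-1, i) x [j-1, j); reported coordinates are continuous, so a feature
# centred in pixel (1, 1) sits at (0.5, 0.5).

.as_image_matrix <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  m <- as.matrix(img)
  storage.mode(m) <- "double"
  r <- range(m)
  if (r[2] > r[1]) m <- (m - r[1]) / (r[2] - r[1])
  m
}

#' Detect scale-invariant blob keypoints in an intensity image
#'
#' Bright blobs (e.g. stained nuclei) are segmented by Otsu thresholding
#' after light Gaussian smoothing, labelled, and reduced to
#' intensity-weighted centroids with an equivalent-circle radius. The
#' centroid/radius representation is invariant to image scale for
#' well-separated blobs.
#'
#' @param img Numeric matrix (x by y) or `EBImage::Image`.
#' @param smooth_sigma Gaussian pre-smoothing sigma in px (default 1).
#' @param min_area Minimum blob area in px^2 (default 4).
#' @return Data frame with columns `x`, `y` (continuous px), `radius`,
#'   `area`.
#' @export
detect_blobs <- function(img, smooth_sigma = 1, min_area = 4) {
  m <- .as_image_matrix(img)
  im <- EBImage::Image(m)
  if (smooth_sigma > 0) im <- EBImage::gblur(im, sigma = smooth_sigma)
  v <- EBImage::imageData(im)
  th <- .otsu_1d(as.numeric(v))
  bw <- EBImage::bwlabel(EBImage::Image(v > th))
  mom <- EBImage::computeFeatures.moment(bw, ref = im)
  shp <- EBImage::computeFeatures.shape(bw)
  if (is.null(mom) || nrow(mom) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      radius = numeric(0), area = numeric(0)))
  keep <- shp[, "s.area"] >= min_area
  data.frame(
    x = unname(mom[keep, "m.cx"]) - 0.5,
    y = unname(mom[keep, "m.cy"]) - 0.5,
    radius = sqrt(unname(shp[keep, "s.area"]) / pi),
    area = unname(shp[keep, "s.area"])
  )
}

# Scale- and rotation-invariant descriptor of a keypoint's local blob
# constellation: distances to the k nearest keypoints, expressed as
# ratios to the nearest-neighbour distance, plus the angles of those
# neighbours relative to the nearest-neighbour direction.
.blob_descriptors <- function(pts, k = 8L) {
  n <- nrow(pts)
  k <- min(k, n - 1L)
  if (k < 2L) stop("too few keypoints for descriptors", call. = FALSE)
  D <- as.matrix(stats::dist(pts))
  desc <- matrix(NA_real_, n, 3L * (k - 1L))
  for (i in seq_len(n)) {
    ord <- order(D[i, ])[-1L][seq_len(k)]
    v <- sweep(pts[ord, , drop = FALSE], 2L, pts[i, ])
    d <- sqrt(rowSums(v^2))
    ang <- atan2(v[, 2L], v[, 1L])
    rel <- ang - ang[1L]
    desc[i, ] <- c(d[-1L] / d[1L], cos(rel[-1L]), sin(rel[-1L]))
  }
  desc
}

# Nearest-neighbour descriptor matching with Lowe's ratio test.
.match_descriptors <- function(da, db, ratio = 0.75) {
  a2 <- rowSums(da^2)
  b2 <- rowSums(db^2)
  D2 <- outer(a2, b2, "+") - 2 * tcrossprod(da, db)
  D2[D2 < 0] <- 0
  idx_a <- integer(0); idx_b <- integer(0)
  for (i in seq_len(nrow(da))) {
    o <- order(D2[i, ])[1:2]
    if (length(o) < 2L || is.na(o[2L])) next
    if (sqrt(D2[i, o[1L]]) < ratio * sqrt(D2[i, o[2L]])) {
      idx_a <- c(idx_a, i); idx_b <- c(idx_b, o[1L])
    }
  }
  data.frame(idx_a = idx_a, idx_b = idx_b)
}

#' Robust affine estimation by random-sample consensus
#'
#' Repeatedly fits an affine transform to random 3-point samples of the
#' correspondences, keeps the model with the most inliers (residual below
#' `inlier_tol` px), then refines by least squares on the inliers (two
#' rounds).
#'
#' @param src,dst N x 2 matrices of putative corresponding points.
#' @param n_iter Number of random samples (default 500).
#' @param inlier_tol Inlier residual threshold in px (default 3).
#' @param min_inliers Minimum inliers for success (default 3).
#' @param seed RNG seed for sampling (default 0); the caller's RNG state
#'   is preserved.
#' @return List with `transform` ([affine2d()]), `inliers` (indices),
#'   `rms_residual`.
#' @export
ransac_affine <- function(src, dst, n_iter = 500L, inlier_tol = 3,
                          min_inliers = 3L, seed = 0L) {
  src <- matrix(as.numeric(src), ncol = 2L)
  dst <- matrix(as.numeric(dst), ncol = 2L)
  n <- nrow(src)
  if (n < 3L)
    stop("registration failure: fewer than 3 correspondences", call. = FALSE)
  best <- integer(0)
  .with_seed(seed, {
    for (it in seq_len(n_iter)) {
      s <- sample.int(n, 3L)
      tf <- tryCatch(estimate_affine(src[s, ], dst[s, ]),
                     error = function(e) NULL)
      if (is.null(tf)) next
      err <- sqrt(rowSums((apply_affine(tf, src) - dst)^2))
      inl <- which(err < inlier_tol)
      if (length(inl) > length(best)) best <- inl
    }
  })
  if (length(best) < min_inliers)
    stop("registration failure: only ", length(best),
         " consensus inliers", call. = FALSE)
  inl <- best
  for (round in 1:2) {
    tf <- estimate_affine(src[inl, ], dst[inl, ])
    err <- sqrt(rowSums((apply_affine(tf, src) - dst)^2))
    inl <- which(err < inlier_tol)
  }
  list(transform = tf,
       inliers = inl,
       rms_residual = sqrt(mean(err[inl]^2)))
}

#' Feature-based affine registration of two images of the same scene
#'
#' Detects blob keypoints in both images ([detect_blobs()]), describes
#' each by its local keypoint constellation (scale- and
#' rotation-invariant), matches descriptors by nearest neighbour with a
#' ratio test, and estimates a robust affine transform from image A to
#' image B by random-sample consensus refined with least squares.
#'
#' @param img_a,img_b Intensity images (matrix x-by-y or
#'   `EBImage::Image`) showing the same scene, e.g. the nuclei channel of
#'   the alignment and high-resolution imaging rounds.
#' @param k_neighbors Constellation size per descriptor (default 8).
#' @param ratio Ratio-test threshold (default 0.75).
#' @param inlier_tol,n_iter,min_inliers,seed Passed to [ransac_affine()].
#' @param smooth_sigma,min_area Passed to [detect_blobs()].
#' @return List of class `feature_registration`: `transform`
#'   ([affine2d()] mapping A px to B px), `n_inliers`, `n_matches`,
#'   `rms_residual`, `n_keypoints` (length-2).
#' @export
register_feature_based <- function(img_a, img_b, k_neighbors = 8L,
                                   ratio = 0.75, inlier_tol = 3,
                                   n_iter = 500L, min_inliers = 3L,
                                   seed = 0L, smooth_sigma = 1,
                                   min_area = 4) {
  ba <- detect_blobs(img_a, smooth_sigma = smooth_sigma, min_area = min_area)
  bb <- detect_blobs(img_b, smooth_sigma = smooth_sigma, min_area = min_area)
  if (nrow(ba) <= k_neighbors || nrow(bb) <= k_neighbors)
    stop("registration failure: too few keypoints (",
         nrow(ba), ", ", nrow(bb), ")", call. = FALSE)
  pa <- as.matrix(ba[, c("x", "y")])
  pb <- as.matrix(bb[, c("x", "y")])
  da <- .blob_descriptors(pa, k = k_neighbors)
  db <- .blob_descriptors(pb, k = k_neighbors)
  m <- .match_descriptors(da, db, ratio = ratio)
  fit <- ransac_affine(pa[m$idx_a, , drop = FALSE],
                       pb[m$idx_b, , drop = FALSE],
                       n_iter = n_iter, inlier_tol = inlier_tol,
                       min_inliers = min_inliers, seed = seed)
  structure(list(transform = fit$transform,
                 n_inliers = length(fit$inliers),
                 n_matches = nrow(m),
                 rms_residual = fit$rms_residual,
                 n_keypoints = c(nrow(ba), nrow(bb))),
            class = "feature_registration")
}

#' @export
print.feature_registration <- function(x, ...) {
  cat(sprintf(
    "feature_registration: %d/%d matches inlying, RMS residual %.3f px\n",
    x$n_inliers, x$n_matches, x$rms_residual))
  print(x$transform)
  invisible(x)
}

# Minimum-area bounding rectangle of a point set (rotating calipers over
# convex hull edges). Returns the 4 corners, unordered.
.min_area_rect <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  best <- NULL; best_area <- Inf
  for (e in seq_len(nh)) {
    p1 <- hp[e, ]; p2 <- hp[if (e == nh) 1L else e + 1L, ]
    v <- p2 - p1
    len <- sqrt(sum(v^2))
    if (len == 0) next
    u <- v / len
    w <- c(-u[2L], u[1L])
    proj_u <- hp %*% u
    proj_w <- hp %*% w
    du <- range(proj_u); dw <- range(proj_w)
    area <- diff(du) * diff(dw)
    if (area < best_area) {
      best_area <- area
      corners_uw <- rbind(c(du[1], dw[1]), c(du[2], dw[1]),
                          c(du[2], dw[2]), c(du[1], dw[2]))
      best <- corners_uw %*% rbind(u, w)
    }
  }
  best
}

#' Detect the alignment-mark frame corners in an image
#'
#' The outermost chip channels are filled with a fluorescent marker and
#' form a square frame around each capture area. The frame is segmented
#' by Otsu thresholding and morphological closing, the largest connected
#' component is taken as the frame, and its minimum-area bounding
#' rectangle yields the four outer corners, labelled `TL`, `TR`, `BR`,
#' `BL` by their position relative to the frame centre.
#'
#' A manual-points table (columns `label`, `x_px`, `y_px`) overrides
#' detection, mirroring interactive vertex picking.
#'
#' @param img Marker-channel image (matrix x-by-y or `EBImage::Image`).
#' @param manual_points Optional data frame of hand-picked vertices.
#' @param closing_size Structuring-element diameter in px (default 5).
#' @param min_frame_area Minimum component area in px^2 to accept as the
#'   frame (default 100).
#' @return Data frame `label`, `x_px`, `y_px` with 4 rows.
#' @export
detect_marker_vertices <- function(img, manual_points = NULL,
                                   closing_size = 5L, min_frame_area = 100) {
  if (!is.null(manual_points)) {
    mp <- as.data.frame(manual_points)
    stopifnot(all(c("label", "x_px", "y_px") %in% names(mp)))
    return(mp[, c("label", "x_px", "y_px")])
  }
  m <- .as_image_matrix(img)
  th <- .otsu_1d(as.numeric(m))
  bw <- EBImage::Image(m > th)
  brush <- EBImage::makeBrush(max(3L, closing_size), shape = "disc")
  bw <- EBImage::closing(bw, brush)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(sizes) == 0L || max(sizes) < min_frame_area)
    stop("alignment frame not found; supply manual_points", call. = FALSE)
  k <- which.max(sizes)
  idx <- which(EBImage::imageData(lab) == k, arr.ind = TRUE)
  pts <- cbind(idx[, 1L] - 0.5, idx[, 2L] - 0.5)
  corners <- .min_area_rect(pts)
  ctr <- colMeans(corners)
  ang <- atan2(corners[, 2L] - ctr[2L], corners[, 1L] - ctr[1L])
  ord <- order(ang)  # -pi..pi: TL, TR, BR, BL on a y-down raster
  data.frame(label = c("TL", "TR", "BR", "BL"),
             x_px = corners[ord, 1L], y_px = corners[ord, 2L],
             stringsAsFactors = FALSE)
}

#' Reference micrometre positions of the alignment-frame corners
#'
#' The frame spans from the outer edge of channel 0 to the outer edge of
#' channel `n_channels - 1`, a square of side
#' `(n_channels - 1) * pitch + channel_width`. Corners are returned in
#' the same `TL`/`TR`/`BR`/`BL` labelling as [detect_marker_vertices()],
#' relative to the capture-area origin (plus the section origin when
#' `well_id` is given).
#'
#' @param layout A [chip_layout()].
#' @param well_id Optional capture area for global coordinates.
#' @return Data frame `label`, `x_um`, `y_um`.
#' @export
marker_reference_points <- function(layout, well_id = NULL) {
  stopifnot(inherits(layout, "chip_layout"))
  W <- (layout$n_channels - 1L) * layout$pitch + layout$channel_width
  off <- c(0, 0)
  if (!is.null(well_id)) {
    i <- match(well_id, layout$section_origins$well_id)
    if (is.na(i)) stop("unknown well_id", call. = FALSE)
    off <- c(layout$section_origins$x0[i], layout$section_origins$y0[i])
  }
  data.frame(label = c("TL", "TR", "BR", "BL"),
             x_um = off[1] + c(0, W, W, 0),
             y_um = off[2] + c(0, 0, W, W),
             stringsAsFactors = FALSE)
}

#' Mean image intensity over each projected spot polygon
#'
#' For every spot, averages the intensity of pixels whose centres fall
#' inside the spot's projected quadrilateral. Spots without any covered
#' pixel get `NA`.
#'
#' @param img Intensity image (matrix x-by-y or `EBImage::Image`),
#'   *not* re-normalized.
#' @param projection Result of [project_spots()].
#' @return Named numeric vector of per-spot means (names = spot_id).
#' @export
spot_mean_intensity <- function(img, projection) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  m <- as.matrix(img)
  co <- projection$corners
  ids <- unique(co$spot_id)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (s in ids) {
    q <- co[co$spot_id == s, c("px_x", "px_y")]
    xr <- range(q$px_x); yr <- range(q$px_y)
    xi <- seq(max(1L, floor(xr[1] + 0.5)), min(nrow(m), ceiling(xr[2] + 0.5)))
    yi <- seq(max(1L, floor(yr[1] + 0.5)), min(ncol(m), ceiling(yr[2] + 0.5)))
    if (length(xi) == 0L || length(yi) == 0L) next
    px <- cbind(rep(xi, times = length(yi)) - 0.5,
                rep(yi, each = length(xi)) - 0.5)
    inside <- .in_convex_quad(px, as.matrix(q))
    if (!any(inside)) next
    out[s] <- mean(m[cbind(rep(xi, times = length(yi))[inside],
                           rep(yi, each = length(xi))[inside])])
  }
  out
}

# Points inside a convex quadrilateral (either winding): all edge
# cross-products share one sign.
.in_convex_quad <- function(pts, quad) {
  sgn <- matrix(0, nrow(pts), 4L)
  for (e in 1:4) {
    a <- quad[e, ]; b <- quad[if (e == 4L) 1L else e + 1L, ]
    sgn[, e] <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
      (b[2] - a[2]) * (pts[, 1] - a[1])
  }
  rowSums(sgn >= 0) == 4L | rowSums(sgn <= 0) == 4L
}
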