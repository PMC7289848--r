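#' Cdc42-GTP cluster intensity threshold
#'
#' Median plus two standard deviations (population SD, divisor n) of the
#' fluorescence intensities within the cell mask. Pixels outside the mask do
#' not contribute. The threshold is equivariant under positive rescaling of
#' the intensities.
#'
#' @param image Numeric matrix, a.u.
#' @param mask A [cell_mask()] or logical matrix.
#' @return Threshold, a.u.
#' @export
cluster_threshold <- function(image, mask) {
  m <- as_mask_matrix(mask)
  stopifnot(identical(dim(image), dim(m)))
  v <- image[m]
  if (length(v) == 0L) stop("empty mask", call. = FALSE)
  stats::median(v) + 2 * sqrt(mean((v - mean(v))^2))
}

# Cluster membership of one frame: in-mask pixels strictly above the
# per-frame threshold.
cluster_pixels <- function(image, mask) {
  m <- as_mask_matrix(mask)
  thr <- cluster_threshold(image, m)
  image > thr & m
}

#' Cdc42-GTP cluster area
#'
#' Computed over the three frames centered on peak Cdc42-GTP localization:
#' per frame, the cluster is the set of in-mask pixels strictly above that
#' frame's median + 2 SD threshold; the area is the median per-frame pixel
#' count converted by `pixel_size^2`. Cluster membership is restricted to
#' the cell mask to exclude bleed-through from neighboring cells.
#'
#' @param images List of frames (numeric matrices), typically 3.
#' @param masks A single [cell_mask()] (or logical matrix) shared by all
#'   frames, or a list of per-frame masks.
#' @param pixel_size Pixel calibration, um/px.
#' @return A list with `area_um2`, `n_px` (median pixel count), `valid`.
#' @export
cluster_area <- function(images, masks, pixel_size) {
  stopifnot(is.list(images), length(images) >= 1L)
  check_positive(pixel_size, "pixel_size")
  if (!is.list(masks) || inherits(masks, "cell_mask")) {
    masks <- rep(list(masks), length(images))
  }
  counts <- mapply(function(img, msk) sum(cluster_pixels(img, msk)),
                   images, masks)
  if (all(counts == 0)) {
    return(list(area_um2 = NA_real_, n_px = 0, valid = FALSE))
  }
  n <- stats::median(counts)
  list(area_um2 = n * pixel_size^2, n_px = n, valid = TRUE)
}

#' Moment axes of the Cdc42-GTP cluster
#'
#' Major and minor axis lengths of the moment-equivalent ellipse of the
#' largest 8-connected component of the cluster pixels.
#'
#' @param cluster Logical matrix of cluster membership (e.g. from one frame
#'   of [cluster_area()]'s thresholding).
#' @param pixel_size Pixel calibration, um/px.
#' @return A list with `major_um`, `minor_um`, `valid`.
#' @export
cluster_axes <- function(cluster, pixel_size) {
  stopifnot(is.matrix(cluster))
  check_positive(pixel_size, "pixel_size")
  if (!any(cluster)) {
    return(list(major_um = NA_real_, minor_um = NA_real_, valid = FALSE))
  }
  lab <- label_components(cluster)
  areas <- tabulate(lab[lab > 0L])
  best <- which.max(areas)
  mom <- region_moments(which(lab == best, arr.ind = TRUE))
  list(major_um = mom$major_px * pixel_size,
       minor_um = mom$minor_px * pixel_size, valid = TRUE)
}

#' Cdc42-GTP cluster length along the cell contour
#'
#' The contour-profile measure of cluster size: per frame, a 5 x 5 maximum
#' filter compensates for the inward shift of the cortical signal, the
#' fluorescence is sampled at the contour vertices (65 by convention), and
#' the profiles are averaged over the three frames around peak
#' localization. The threshold is the median of the three per-frame
#' median + 2 SD thresholds; the cluster length is the circular arc length
#' of the contiguous suprathreshold run containing the profile maximum.
#'
#' @param images List of frames (numeric matrices), typically 3.
#' @param contour Two-column matrix (x, y) of ordered closed-contour
#'   vertices, px (use [resample_contour()] for the 65-vertex convention).
#' @param mask A [cell_mask()] or logical matrix used for the per-frame
#'   thresholds.
#' @param pixel_size Pixel calibration, um/px.
#' @return A list with `length_um`, `valid`, and the mean `profile`.
#' @export
cluster_contour_length <- function(images, contour, mask, pixel_size) {
  stopifnot(is.list(images), length(images) >= 1L, is.matrix(contour))
  check_positive(pixel_size, "pixel_size")
  thr <- stats::median(vapply(images, cluster_threshold, numeric(1),
                              mask = mask))
  profs <- vapply(images, function(img) {
    f <- max_filter(img, 5L)
    bilinear_sample(f, contour[, 1], contour[, 2])
  }, numeric(nrow(contour)))
  prof <- rowMeans(profs)
  if (!any(prof > thr)) {
    return(list(length_um = NA_real_, valid = FALSE, profile = prof))
  }
  seg <- contour_arclength(contour)
  w <- circular_width_above(prof, thr, which.max(prof), seg$s, seg$perim)
  list(length_um = w * pixel_size, valid = TRUE, profile = prof)
}

#' Resample a closed contour to equally spaced vertices
#'
#' Linear interpolation along the polygon at `n` equally spaced arc-length
#' positions, starting at the first vertex. The published contour-profile
#' measurements use 65 vertices.
#'
#' @param contour Two-column matrix (x, y) of ordered closed-contour
#'   vertices.
#' @param n Number of output vertices.
#' @return An `n` x 2 matrix (x, y).
#' @export
resample_contour <- function(contour, n = 65L) {
  stopifnot(is.matrix(contour), nrow(contour) >= 3L)
  n <- check_count(n, "n", min = 3L)
  closed <- rbind(contour, contour[1L, ])
  d <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(d))
  target <- seq(0, s[length(s)], length.out = n + 1L)[seq_len(n)]
  x <- stats::approx(s, closed[, 1], xout = target)$y
  y <- stats::approx(s, closed[, 2], xout = target)$y
  cbind(x = x, y = y)
}

#' Algebraic (Kasa) least-squares circle fit
#'
#' Linear least squares on `x^2 + y^2 = 2 a x + 2 b y + c`; exact on points
#' lying on a circle, deterministic, with the RMS radial residual reported
#' for quality control. Collinear points give a singular system and raise a
#' degenerate-fit error.
#'
#' @param xy Two-column matrix of point coordinates.
#' @return A list with `center` (x, y), `radius`, `residual` (RMS radial
#'   misfit, same units as the input).
#' @export
fit_circle <- function(xy) {
  stopifnot(is.matrix(xy), nrow(xy) >= 3L)
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  q <- qr(A)
  if (q$rank < 3L) stop("degenerate circle fit: points are collinear",
                        call. = FALSE)
  beta <- qr.coef(q, b)
  r2 <- beta[3] + beta[1]^2 + beta[2]^2
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate circle fit", call. = FALSE)
  }
  r <- sqrt(r2)
  dist <- sqrt((x - beta[1])^2 + (y - beta[2])^2)
  list(center = c(x = unname(beta[1]), y = unname(beta[2])),
       radius = unname(r),
       residual = sqrt(mean((dist - r)^2)))
}

#' Local radius of cell curvature at the incipient bud site
#'
#' Fits a circle (Kasa algebraic fit) to the `window` contour vertices
#' centered on the anchor vertex (the position of the maximum septin
#' signal), circularly indexed. Coordinates are converted to um before
#' fitting.
#'
#' @param contour Two-column matrix (x, y) of ordered closed-contour
#'   vertices, px.
#' @param anchor Anchor vertex index.
#' @param window Number of vertices in the fit (odd; 7 by convention).
#' @param pixel_size Pixel calibration, um/px.
#' @return A list with `radius_um` and `residual_um`.
#' @export
local_curvature_radius <- function(contour, anchor, window = 7L,
                                   pixel_size = 1) {
  stopifnot(is.matrix(contour), nrow(contour) >= window, window %% 2 == 1)
  check_positive(pixel_size, "pixel_size")
  n <- nrow(contour)
  anchor <- check_count(anchor, "anchor")
  if (anchor > n) stop("'anchor' exceeds the number of vertices",
                       call. = FALSE)
  r <- (window - 1L) / 2L
  idx <- ((anchor - 1L + (-r:r)) %% n) + 1L
  fit <- fit_circle(contour[idx, , drop = FALSE] * pixel_size)
  list(radius_um = fit$radius, residual_um = fit$residual)
}

#' Median local curvature radius over frames
#'
#' The per-frame curvature radii (circle fit at the per-frame anchor) are
#' summarized by their median over the frames centered on bud emergence
#' (five by convention).
#'
#' @param contours List of per-frame contours (two-column matrices, px).
#' @param anchors Per-frame anchor vertex indices (recycled if length 1).
#' @inheritParams local_curvature_radius
#' @return Median radius, um.
#' @export
median_curvature_radius <- function(contours, anchors, window = 7L,
                                    pixel_size = 1) {
  stopifnot(is.list(contours))
  anchors <- rep_len(anchors, length(contours))
  stats::median(mapply(function(ct, an) {
    local_curvature_radius(ct, an, window, pixel_size)$radius_um
  }, contours, anchors))
}
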