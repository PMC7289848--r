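#' Per-frame binary cell mask
#'
#' Container for one cell's segmentation in one frame: a binary pixel grid,
#' the pixel calibration, and optionally an ordered closed contour in pixel
#' coordinates. The foreground must be non-empty and form a single
#' 8-connected component.
#'
#' @param mask Logical (or 0/1 numeric) matrix; `TRUE` = cell.
#' @param pixel_size Pixel calibration, um/px.
#' @param frame Frame index.
#' @param cell_id Cell identifier.
#' @param contour Optional two-column matrix (x, y) of ordered contour
#'   vertices, px.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(mask, pixel_size, frame = 1L, cell_id = "cell",
                      contour = NULL) {
  if (is.numeric(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  check_positive(pixel_size, "pixel_size")
  lab <- label_components(mask)
  if (max(lab) > 1L) {
    stop("mask must contain a single connected component", call. = FALSE)
  }
  structure(list(mask = mask, pixel_size = pixel_size,
                 frame = as.integer(frame), cell_id = cell_id,
                 contour = contour),
            class = "cell_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "cell_mask")) mask$mask else mask
}

mask_pixel_size <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "cell_mask")) return(mask$pixel_size)
  if (is.null(pixel_size)) stop("'pixel_size' required for a bare matrix",
                                call. = FALSE)
  pixel_size
}

# Principal-axis rotation of foreground pixel-center coordinates; returns
# coordinates (u along major axis, v perpendicular), in px.
principal_frame_coords <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
  y <- idx[, 1]; x <- idx[, 2]
  cx <- mean(x); cy <- mean(y)
  uxx <- mean((x - cx)^2); uyy <- mean((y - cy)^2)
  uxy <- mean((x - cx) * (y - cy))
  theta <- if (uxy == 0 && uxx >= uyy) 0 else atan2(2 * uxy, uxx - uyy) / 2
  ct <- cos(theta); st <- sin(theta)
  list(u = (x - cx) * ct + (y - cy) * st,
       v = -(x - cx) * st + (y - cy) * ct)
}

#' Cell volume by solid of revolution
#'
#' Rotates the foreground pixel centers into the major-axis frame, bins them
#' into 1-px slices perpendicular to the major axis, and treats each slice
#' as a cylinder of height 1 px whose diameter is the slice's perpendicular
#' extent (max - min + 1 px). Volumes are returned in fL (1 fL = 1 um^3).
#'
#' @param mask A [cell_mask()] or logical matrix.
#' @param pixel_size Pixel calibration, um/px (taken from the `cell_mask`
#'   when available).
#' @return Volume in fL.
#' @export
revolution_volume <- function(mask, pixel_size = NULL) {
  px <- mask_pixel_size(mask, pixel_size)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("empty mask", call. = FALSE)
  co <- principal_frame_coords(m)
  bin <- floor(co$u - min(co$u))
  widths <- vapply(split(co$v, bin),
                   function(v) diff(range(v)) + 1, numeric(1))
  sum(pi / 4 * widths^2) * px^3
}

#' Cell length along the major axis
#'
#' Length of the major axis of the ellipse with the same normalized second
#' central moments as the mask foreground (the regionprops convention:
#' unit-pixel moments plus 1/12, axis = 4 sqrt(eigenvalue)).
#'
#' @inheritParams revolution_volume
#' @return Length in um.
#' @export
major_axis_length <- function(mask, pixel_size = NULL) {
  px <- mask_pixel_size(mask, pixel_size)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("empty mask", call. = FALSE)
  region_moments(which(m, arr.ind = TRUE))$major_px * px
}

#' Cell elongation
#'
#' Cell length divided by the cube root of cell volume, normalized by
#' (pi/6)^(1/3) so that a sphere scores exactly 1. For a prolate spheroid
#' with aspect ratio a/b the value is (a/b)^(2/3).
#'
#' @param length Cell length, um.
#' @param volume Cell volume, fL.
#' @return Dimensionless elongation (>= 1 up to rasterization tolerance).
#' @export
elongation <- function(length, volume) {
  check_positive(length, "length")
  check_positive(volume, "volume")
  (pi / 6)^(1 / 3) * length / volume^(1 / 3)
}

#' Background-subtracted total cell fluorescence
#'
#' The background is the median pixel value of the non-cell area of the
#' image after a 2 x 2 (four-pixel) average filter; the result is the sum of
#' background-subtracted intensities over the mask. Adding a constant to the
#' whole image leaves the result unchanged.
#'
#' @param image Numeric matrix, a.u.
#' @param mask A [cell_mask()] or logical matrix congruent with `image`.
#' @return Total fluorescence, a.u.
#' @export
total_cell_fluorescence <- function(image, mask) {
  m <- as_mask_matrix(mask)
  stopifnot(identical(dim(image), dim(m)))
  if (all(m)) stop("mask covers the entire image; no background region",
                   call. = FALSE)
  bg <- stats::median(avg4_filter(image)[!m])
  sum(image[m] - bg)
}

#' Li minimum-cross-entropy threshold
#'
#' Iterative fixed point of the Li & Tam minimum-cross-entropy criterion:
#' `t <- (mu_fg - mu_bg) / (log(mu_fg) - log(mu_bg))`, started at the sample
#' mean and iterated to a 1e-6 relative tolerance. Values are shifted to be
#' strictly positive if needed and the shift undone on return. The
#' threshold is equivariant under positive rescaling of the intensities.
#'
#' @param values Numeric vector of intensities.
#' @param tol Relative convergence tolerance.
#' @return Threshold on the scale of `values`.
#' @export
threshold_li <- function(values, tol = 1e-6) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least two finite values", call. = FALSE)
  offset <- 0
  if (min(v) <= 0) {
    offset <- -min(v) + 1e-9 * max(abs(v), 1)
    v <- v + offset
  }
  t <- mean(v)
  for (i in 1:200) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) break
    mb <- mean(lo); mf <- mean(hi)
    if (mb == mf) break
    t_new <- (mf - mb) / (log(mf) - log(mb))
    if (abs(t_new - t) <= tol * max(t, 1e-12)) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t - offset
}

# Hysteresis thresholding of one slice: pixels above `low` are kept only if
# 8-connected to a pixel above `high`.
hysteresis_slice <- function(slice, low, high) {
  bw <- slice > low
  if (!any(bw)) return(matrix(FALSE, nrow(slice), ncol(slice)))
  lab <- label_components(bw)
  seeds <- unique(lab[slice > high & bw])
  seeds <- seeds[seeds > 0]
  if (length(seeds) == 0L) return(matrix(FALSE, nrow(slice), ncol(slice)))
  matrix(lab %in% seeds, nrow(slice))
}

#' 3D cell volume reconstruction from a confocal z-stack
#'
#' Segments each slice by hysteresis thresholding: foreground pixels are
#' those above a low threshold (Li minimum cross entropy, computed over the
#' whole stack) that are connected to pixels above a high threshold (90% of
#' the slice maximum within the matched widefield 2D mask). The volume is
#' the voxel count times `pixel_size^2 * z_step`.
#'
#' @param zstack 3D numeric array (row x col x slice), a.u.
#' @param mask2d A [cell_mask()] from the matched widefield frame.
#' @param z_step Slice separation, um.
#' @param high_fraction Fraction of the in-mask maximum used as the high
#'   threshold.
#' @return Volume in fL.
#' @export
reconstruct_volume_3d <- function(zstack, mask2d, z_step,
                                  high_fraction = 0.9) {
  stopifnot(length(dim(zstack)) == 3L)
  check_positive(z_step, "z_step")
  px <- mask_pixel_size(mask2d)
  m <- as_mask_matrix(mask2d)
  stopifnot(identical(dim(zstack)[1:2], dim(m)))
  low <- threshold_li(as.vector(zstack))
  voxels <- 0L
  any_seed <- FALSE
  for (k in seq_len(dim(zstack)[3])) {
    slice <- zstack[, , k]
    high <- high_fraction * max(slice[m])
    if (high <= low) next
    fg <- hysteresis_slice(slice, low, high)
    if (any(fg)) any_seed <- TRUE
    voxels <- voxels + sum(fg)
  }
  if (!any_seed) stop("no voxel above the high threshold in any slice",
                      call. = FALSE)
  voxels * px^2 * z_step
}

#' Full geometry of one cell frame
#'
#' Convenience wrapper computing revolution volume, major-axis length and
#' elongation (and, when an image is supplied, total fluorescence) from one
#' mask.
#'
#' @param mask A [cell_mask()].
#' @param image Optional congruent intensity image for total fluorescence.
#' @return A one-row data frame with columns `volume_fL`, `length_um`,
#'   `elongation`, `total_fluor_au`.
#' @export
cell_geometry <- function(mask, image = NULL) {
  vol <- revolution_volume(mask)
  len <- major_axis_length(mask)
  data.frame(volume_fL = vol, length_um = len,
             elongation = elongation(len, vol),
             total_fluor_au = if (is.null(image)) NA_real_
                              else total_cell_fluorescence(image, mask))
}
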