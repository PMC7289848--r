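#' Detect the bud-neck ring in a fluorescence frame
#'
#' Binarizes the image at a fixed threshold (set per dataset), labels
#' 8-connected components, rejects components smaller than `min_area`
#' pixels, and fits a moment-equivalent ellipse to the largest surviving
#' component. Absence of a detection is a valid outcome (`NULL`), not an
#' error. Area ties are broken by the lowest component label.
#'
#' @param image Numeric matrix, a.u.
#' @param threshold Binarization threshold, a.u. (> 0).
#' @param min_area Minimal ring area in pixels (default 10).
#' @param frame Frame index carried into the detection.
#' @return A `ring_detection` (center, orientation in \[-pi/2, pi/2), axis
#'   lengths in px, component area, frame), or `NULL`.
#' @export
detect_ring <- function(image, threshold, min_area = 10L, frame = 1L) {
  check_positive(threshold, "threshold")
  bw <- image > threshold
  if (!any(bw)) return(NULL)
  lab <- label_components(bw)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(NULL)
  best <- keep[which.max(areas[keep])]  # which.max takes the first on ties
  mom <- region_moments(which(lab == best, arr.ind = TRUE))
  structure(list(center = mom$centroid, orientation = mom$orientation,
                 major_px = mom$major_px, minor_px = mom$minor_px,
                 area_px = mom$area_px, frame = as.integer(frame)),
            class = "ring_detection")
}

#' Construct an intensity profile
#'
#' One-dimensional fluorescence samples along a line (or contour) with
#' uniform spacing, plus provenance flags recording whether the profile has
#' been smoothed and background-subtracted.
#'
#' @param positions Sample positions, px (uniformly spaced).
#' @param values Sample values, a.u.
#' @param spacing Sample spacing, px.
#' @param smoothed,background_subtracted Provenance flags.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, values, spacing = 1,
                              smoothed = FALSE,
                              background_subtracted = FALSE) {
  stopifnot(length(positions) == length(values), spacing > 0)
  structure(list(positions = positions, values = values, spacing = spacing,
                 smoothed = smoothed,
                 background_subtracted = background_subtracted),
            class = "intensity_profile")
}

new_profile <- intensity_profile

#' Extract the ring line profile
#'
#' Samples the fluorescence image along the major axis of the fitted ring
#' ellipse, `half_length` px on each side of the ellipse center
#' (2 * half_length + 1 samples, 1 px spacing). Each sample is the mean of
#' `avg_width` bilinear samples spaced 1 px apart perpendicular to the axis,
#' centered on the line. Samples falling outside the image are clamped to
#' the border with a warning.
#'
#' @param image Numeric matrix, a.u.
#' @param detection A `ring_detection` from [detect_ring()].
#' @param half_length Half profile length, px (30; 60 for large-cell
#'   strains).
#' @param avg_width Perpendicular averaging width, px.
#' @return An `intensity_profile` with positions in px relative to the
#'   ellipse center.
#' @export
extract_profile <- function(image, detection, half_length = 30L,
                            avg_width = 10L) {
  if (is.null(detection)) stop("no ring detection", call. = FALSE)
  stopifnot(inherits(detection, "ring_detection"))
  half_length <- check_count(half_length, "half_length")
  avg_width <- check_count(avg_width, "avg_width")
  s <- seq(-half_length, half_length, by = 1)
  t <- seq_len(avg_width) - (avg_width + 1) / 2
  th <- detection$orientation
  ux <- cos(th); uy <- sin(th)
  vx <- -sin(th); vy <- cos(th)
  X <- outer(s, t, function(si, ti) detection$center[["x"]] + si * ux +
               ti * vx)
  Y <- outer(s, t, function(si, ti) detection$center[["y"]] + si * uy +
               ti * vy)
  if (min(X) < 1 || max(X) > ncol(image) || min(Y) < 1 ||
      max(Y) > nrow(image)) {
    warning("profile line clipped to the image border")
  }
  vals <- matrix(bilinear_sample(image, as.vector(X), as.vector(Y)),
                 nrow = length(s))
  new_profile(s, rowMeans(vals))
}

#' Gliding-average smoothing of a profile
#'
#' Three-sample moving mean with a shrinking window at the profile ends (so
#' the profile length, used by the outermost-background rule, is preserved).
#'
#' @param profile An `intensity_profile`.
#' @param window Moving-average window, samples (odd).
#' @return The smoothed `intensity_profile`.
#' @export
smooth_profile <- function(profile, window = 3L) {
  stopifnot(inherits(profile, "intensity_profile"), window %% 2 == 1)
  v <- profile$values
  n <- length(v)
  r <- (window - 1L) / 2L
  out <- vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - r):min(n, i + r)])
  }, numeric(1))
  new_profile(profile$positions, out, profile$spacing, smoothed = TRUE,
              background_subtracted = profile$background_subtracted)
}

#' Subtract the outermost-sample background from a profile
#'
#' The background is the mean of the three samples most distant from the
#' center on each side (six samples in total); it is subtracted from the
#' whole profile. Adding a constant to the raw profile therefore leaves the
#' result unchanged.
#'
#' @param profile An `intensity_profile` with at least 7 samples.
#' @param n_outer Number of outermost samples per side.
#' @return The background-subtracted `intensity_profile`.
#' @export
subtract_background <- function(profile, n_outer = 3L) {
  stopifnot(inherits(profile, "intensity_profile"))
  v <- profile$values
  if (length(v) < 2L * n_outer + 1L) {
    stop("profile too short for background estimation", call. = FALSE)
  }
  bg <- mean(c(utils::head(v, n_outer), utils::tail(v, n_outer)))
  new_profile(profile$positions, v - bg, profile$spacing,
              smoothed = profile$smoothed, background_subtracted = TRUE)
}

#' Smooth a profile and subtract its background
#'
#' The standard preprocessing before the full-width-at-half-maximum
#' measurement: 3-sample gliding average, then subtraction of the mean of
#' the three outermost smoothed samples per side.
#'
#' @inheritParams subtract_background
#' @return The processed `intensity_profile`.
#' @export
smooth_subtract_background <- function(profile, window = 3L, n_outer = 3L) {
  if (length(profile$values) < 7L) {
    stop("profile must have at least 7 samples", call. = FALSE)
  }
  subtract_background(smooth_profile(profile, window), n_outer)
}

#' Ring diameter as profile full width at half maximum
#'
#' On a background-subtracted profile, finds the positions where the
#' profile first rises above half of its maximum, scanning inward from each
#' end, with sub-pixel linear interpolation between the bracketing samples.
#' The diameter is the distance between the two crossings. The measurement
#' is flagged invalid when the maximum is not positive or when the signal
#' touches a profile end (no crossing on that side).
#'
#' @param profile A background-subtracted `intensity_profile`.
#' @param pixel_size Pixel calibration, um/px.
#' @return A list with `diameter_um`, `valid`, and the crossing positions
#'   `left_px`, `right_px` (profile coordinates).
#' @export
fwhm_diameter <- function(profile, pixel_size) {
  stopifnot(inherits(profile, "intensity_profile"))
  check_positive(pixel_size, "pixel_size")
  v <- profile$values
  p <- profile$positions
  m <- max(v)
  invalid <- list(diameter_um = NA_real_, valid = FALSE,
                  left_px = NA_real_, right_px = NA_real_)
  if (!is.finite(m) || m <= 0) return(invalid)
  half <- m / 2
  iL <- which(v >= half)[1]
  iR <- length(v) + 1L - which(rev(v) >= half)[1]
  if (iL <= 1L || iR >= length(v)) return(invalid)
  xl <- p[iL - 1L] + (half - v[iL - 1L]) / (v[iL] - v[iL - 1L]) *
    (p[iL] - p[iL - 1L])
  xr <- p[iR + 1L] - (half - v[iR + 1L]) / (v[iR] - v[iR + 1L]) *
    (p[iR + 1L] - p[iR])
  list(diameter_um = (xr - xl) * pixel_size, valid = TRUE,
       left_px = xl, right_px = xr)
}

#' Integrated ring line-profile intensity
#'
#' Sum of the background-subtracted profile samples, with negative samples
#' clipped at zero.
#'
#' @param profile A background-subtracted `intensity_profile`.
#' @return Total intensity, a.u.
#' @export
ring_total_intensity <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  sum(pmax(profile$values, 0))
}

#' Measure the ring in one frame
#'
#' Composition of the per-frame measurement: detection, line-profile
#' extraction, gliding-average smoothing and background subtraction, then
#' full width at half maximum and integrated intensity. Returns an invalid
#' measurement (not an error) when no ring is detected.
#'
#' @inheritParams detect_ring
#' @inheritParams extract_profile
#' @param pixel_size Pixel calibration, um/px.
#' @return A one-row data frame: `frame`, `d_um`, `intensity_au`, `valid`.
#' @export
measure_ring <- function(image, threshold, pixel_size, min_area = 10L,
                         half_length = 30L, avg_width = 10L, frame = 1L) {
  det <- detect_ring(image, threshold, min_area = min_area, frame = frame)
  if (is.null(det)) {
    return(data.frame(frame = as.integer(frame), d_um = NA_real_,
                      intensity_au = NA_real_, valid = FALSE))
  }
  prof <- smooth_subtract_background(
    extract_profile(image, det, half_length, avg_width))
  fw <- fwhm_diameter(prof, pixel_size)
  data.frame(frame = as.integer(frame), d_um = fw$diameter_um,
             intensity_au = if (fw$valid) ring_total_intensity(prof)
                            else NA_real_,
             valid = fw$valid)
}

# Circular FWHM on a closed contour profile: arc-length width of the region
# above `level`, around the peak at index `i0`. `s` is the cumulative
# arc-length coordinate of the vertices; `perim` the closed perimeter.
circular_width_above <- function(values, level, i0, s, perim) {
  n <- length(values)
  stopifnot(length(s) == n)
  step_s <- function(i, di) ((i - 1L + di) %% n) + 1L
  arc <- function(i, j) (s[j] - s[i]) %% perim  # forward arc i -> j
  # walk left from the peak to the first vertex below level
  iL <- i0; kL <- 0L
  repeat {
    nxt <- step_s(iL, -1L)
    if (values[nxt] < level || kL >= n) break
    iL <- nxt; kL <- kL + 1L
  }
  iR <- i0; kR <- 0L
  repeat {
    nxt <- step_s(iR, 1L)
    if (values[nxt] < level || kR >= n) break
    iR <- nxt; kR <- kR + 1L
  }
  if (kL >= n || kR >= n) return(perim)  # whole contour above level
  bL <- step_s(iL, -1L); bR <- step_s(iR, 1L)
  fracL <- (values[iL] - level) / (values[iL] - values[bL])
  fracR <- (values[iR] - level) / (values[iR] - values[bR])
  arc(iL, iR) + fracL * arc(bL, iL) + fracR * arc(iR, bR)
}

#' Contour-profile ring diameter
#'
#' The bud-emergence variant of the diameter measurement: each frame is
#' smoothed with a 3 x 3 mean filter, the fluorescence is sampled at the
#' cell-contour vertices, and the profiles are averaged over the frames
#' (five frames centered on bud emergence). With the profile minimum as the
#' baseline, the diameter is the circular arc-length full width at half
#' maximum around the profile peak. A flat profile is flagged invalid.
#'
#' @param images List of frames (numeric matrices) centered on bud
#'   emergence.
#' @param contour Two-column matrix (x, y) of ordered closed-contour
#'   vertices, px (typically 65).
#' @param pixel_size Pixel calibration, um/px.
#' @return A list with `diameter_um`, `valid`, and the vertex-sampled
#'   `profile`.
#' @export
contour_ring_diameter <- function(images, contour, pixel_size) {
  stopifnot(is.list(images), length(images) >= 1L, is.matrix(contour))
  check_positive(pixel_size, "pixel_size")
  profs <- vapply(images, function(img) {
    f <- mean_filter(img, 3L)
    bilinear_sample(f, contour[, 1], contour[, 2])
  }, numeric(nrow(contour)))
  prof <- rowMeans(profs)
  baseline <- min(prof)
  # flat to numerical precision: no peak to measure
  if (max(prof) - baseline <= 1e-9 * max(1, abs(baseline))) {
    return(list(diameter_um = NA_real_, valid = FALSE, profile = prof))
  }
  level <- baseline + (max(prof) - baseline) / 2
  seg <- contour_arclength(contour)
  w <- circular_width_above(prof, level, which.max(prof), seg$s, seg$perim)
  list(diameter_um = w * pixel_size, valid = TRUE, profile = prof)
}

# Cumulative arc-length coordinate of closed-contour vertices (s[1] = 0) and
# the total perimeter, in px.
contour_arclength <- function(contour) {
  d <- sqrt(rowSums((contour - contour[c(2:nrow(contour), 1L), ])^2))
  list(s = cumsum(c(0, d[-length(d)])), perim = sum(d))
}
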