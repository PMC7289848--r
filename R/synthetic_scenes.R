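#' Configuration for a synthetic cell population
#'
#' Defines the study conditions for a steady-state population of budding
#' yeast cells: a lognormal cell-volume distribution (volumes in fL; 1 fL =
#' 1 um^3), prolate-spheroid cell shapes with a truncated-normal aspect
#' ratio, and a bud-neck ring whose ground-truth diameter follows a power
#' law of volume, `d = c * V^alpha`, with multiplicative lognormal noise.
#'
#' Defaults emulate haploid cells spanning roughly 30-300 fL with a scaling
#' exponent of 0.31, i.e. a population pooled over small and large
#' steady-state volumes on a respiratory carbon source.
#'
#' @param n_cells Number of cells (>= 1).
#' @param volume_median Median cell volume, fL.
#' @param volume_log10_sd Standard deviation of log10(volume).
#' @param exponent_alpha Ground-truth scaling exponent alpha.
#' @param prefactor_c Ground-truth prefactor c, um * fL^(-alpha).
#' @param diameter_noise_cv Coefficient of variation of the multiplicative
#'   lognormal diameter noise (0 = noiseless).
#' @param aspect_ratio_mean,aspect_ratio_sd Mean and sd of the prolate
#'   aspect ratio a/b, truncated at 1 (a sphere).
#' @param cluster_prefactor,cluster_exponent Ground-truth Cdc42 cluster
#'   diameter law, `d_cluster = cluster_prefactor * V^cluster_exponent`.
#' @param pixel_size Pixel calibration, um/px.
#' @param seed Integer RNG seed; identical seed and config give a
#'   byte-identical population.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_cells = 300L,
                              volume_median = 95,
                              volume_log10_sd = 0.25,
                              exponent_alpha = 0.31,
                              prefactor_c = 0.34,
                              diameter_noise_cv = 0.10,
                              aspect_ratio_mean = 1.2,
                              aspect_ratio_sd = 0.1,
                              cluster_prefactor = 0.30,
                              cluster_exponent = 1 / 3,
                              pixel_size = 0.1,
                              seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  check_positive(volume_median, "volume_median")
  check_nonnegative(volume_log10_sd, "volume_log10_sd")
  check_positive(prefactor_c, "prefactor_c")
  check_nonnegative(diameter_noise_cv, "diameter_noise_cv")
  check_positive(aspect_ratio_mean, "aspect_ratio_mean")
  check_nonnegative(aspect_ratio_sd, "aspect_ratio_sd")
  if (aspect_ratio_mean < 1) stop("'aspect_ratio_mean' must be >= 1",
                                  call. = FALSE)
  check_positive(cluster_prefactor, "cluster_prefactor")
  check_positive(pixel_size, "pixel_size")
  structure(list(n_cells = n_cells, volume_median = volume_median,
                 volume_log10_sd = volume_log10_sd,
                 exponent_alpha = exponent_alpha, prefactor_c = prefactor_c,
                 diameter_noise_cv = diameter_noise_cv,
                 aspect_ratio_mean = aspect_ratio_mean,
                 aspect_ratio_sd = aspect_ratio_sd,
                 cluster_prefactor = cluster_prefactor,
                 cluster_exponent = cluster_exponent,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "population_config")
}

#' Rendering configuration for synthetic fluorescence frames
#'
#' Image-formation parameters: Gaussian point-spread function, constant
#' background with Gaussian read noise (optionally Poisson shot noise), the
#' bud-neck ring rendered as a uniform-intensity bar viewed edge-on, a
#' cortical Cdc42 cluster spot, and timecourse event frames. The cluster
#' peak must precede bud emergence.
#'
#' @param psf_sigma Gaussian PSF sigma, px.
#' @param background_level Constant background, a.u.
#' @param read_noise_sd Gaussian read noise sd, a.u. (0 = noiseless).
#' @param shot_noise If `TRUE`, add Poisson shot noise on the signal.
#' @param ring_peak_intensity Ring bar amplitude above background, a.u.
#' @param cluster_peak_intensity Cdc42 cluster spot amplitude, a.u.
#' @param cytoplasm_intensity Cytoplasmic fill used in z-stacks, a.u.
#' @param ring_thickness_px Bar thickness across the ring, px.
#' @param frame_count_ring Number of frames the ring persists (>= 1).
#' @param cluster_peak_frame Frame index of peak Cdc42 cluster intensity.
#' @param bud_emergence_frame Frame index of bud emergence; must be greater
#'   than `cluster_peak_frame`.
#' @param z_step Confocal z-stack slice separation, um.
#' @return An object of class `render_config`.
#' @export
render_config <- function(psf_sigma = 1,
                          background_level = 100,
                          read_noise_sd = 2,
                          shot_noise = FALSE,
                          ring_peak_intensity = 500,
                          cluster_peak_intensity = 400,
                          cytoplasm_intensity = 300,
                          ring_thickness_px = 3,
                          frame_count_ring = 12L,
                          cluster_peak_frame = 3L,
                          bud_emergence_frame = 6L,
                          z_step = 0.3) {
  check_nonnegative(psf_sigma, "psf_sigma")
  check_nonnegative(background_level, "background_level")
  check_nonnegative(read_noise_sd, "read_noise_sd")
  check_positive(ring_peak_intensity, "ring_peak_intensity")
  check_positive(cluster_peak_intensity, "cluster_peak_intensity")
  check_positive(cytoplasm_intensity, "cytoplasm_intensity")
  check_positive(ring_thickness_px, "ring_thickness_px")
  frame_count_ring <- check_count(frame_count_ring, "frame_count_ring")
  cluster_peak_frame <- check_count(cluster_peak_frame, "cluster_peak_frame")
  bud_emergence_frame <- check_count(bud_emergence_frame,
                                     "bud_emergence_frame")
  if (cluster_peak_frame >= bud_emergence_frame) {
    stop("'cluster_peak_frame' must precede 'bud_emergence_frame'",
         call. = FALSE)
  }
  check_positive(z_step, "z_step")
  structure(list(psf_sigma = psf_sigma, background_level = background_level,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 ring_peak_intensity = ring_peak_intensity,
                 cluster_peak_intensity = cluster_peak_intensity,
                 cytoplasm_intensity = cytoplasm_intensity,
                 ring_thickness_px = ring_thickness_px,
                 frame_count_ring = frame_count_ring,
                 cluster_peak_frame = cluster_peak_frame,
                 bud_emergence_frame = bud_emergence_frame,
                 z_step = z_step),
            class = "render_config")
}

# Construct one synthetic cell from sampled quantities. Semi-axes are chosen
# so that (4/3) pi a b^2 = V exactly, with a/b the prolate aspect ratio.
make_synthetic_cell <- function(volume, aspect, d_ring, d_cluster,
                                orientation, pixel_size, cell_id,
                                generation = 1L) {
  b <- (3 * volume / (4 * pi * aspect))^(1 / 3)
  a <- aspect * b
  structure(list(cell_id = cell_id,
                 volume_true = volume,
                 length_true = 2 * a,
                 ring_diameter_true = d_ring,
                 cluster_diameter_true = d_cluster,
                 semi_major_um = a,
                 semi_minor_um = b,
                 orientation = orientation,
                 generation = as.integer(generation),
                 pixel_size = pixel_size),
            class = "synthetic_cell")
}

#' Generate a synthetic steady-state cell population
#'
#' Draws `n_cells` cells with lognormal volumes, prolate-spheroid shapes and
#' ground-truth ring diameters `d = c * V^alpha` times multiplicative
#' lognormal noise (median-preserving: the log-noise has mean zero). Each
#' cell has its own RNG stream derived from the population seed, so
#' enlarging the population never perturbs earlier cells.
#'
#' @param config A [population_config()].
#' @return A list of `synthetic_cell` objects.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  sdlog <- sqrt(log(1 + config$diameter_noise_cv^2))
  lapply(seq_len(config$n_cells), function(i) {
    set.seed(child_seed(config$seed, i))
    v <- 10^stats::rnorm(1, log10(config$volume_median),
                         config$volume_log10_sd)
    # truncated-normal aspect ratio, >= 1
    repeat {
      asp <- stats::rnorm(1, config$aspect_ratio_mean,
                          config$aspect_ratio_sd)
      if (asp >= 1 || config$aspect_ratio_sd == 0) break
    }
    asp <- max(asp, 1)
    d <- config$prefactor_c * v^config$exponent_alpha *
      exp(stats::rnorm(1, 0, sdlog))
    dc <- config$cluster_prefactor * v^config$cluster_exponent
    theta <- stats::runif(1, -pi / 2, pi / 2)
    make_synthetic_cell(v, asp, d, dc, theta, config$pixel_size,
                        cell_id = sprintf("cell_%04d", i))
  })
}

#' Ground-truth table of a synthetic population
#'
#' @param cells List of `synthetic_cell` objects.
#' @return A data frame with one row per cell (volumes in fL, lengths and
#'   diameters in um).
#' @export
population_truth <- function(cells) {
  data.frame(cell_id = vapply(cells, `[[`, "", "cell_id"),
             volume_true_fL = vapply(cells, `[[`, 0, "volume_true"),
             length_true_um = vapply(cells, `[[`, 0, "length_true"),
             d_true_um = vapply(cells, `[[`, 0, "ring_diameter_true"),
             cluster_d_true_um = vapply(cells, `[[`, 0,
                                        "cluster_diameter_true"),
             generation = vapply(cells, `[[`, 1L, "generation"),
             stringsAsFactors = FALSE)
}

# Rasterize one cell frame. Returns pixel-center coordinate grids rotated
# into the cell frame (u along the major axis, v perpendicular).
cell_raster_frame <- function(cell, extra_halfwidth_px = 0, size = NULL) {
  px <- cell$pixel_size
  a_px <- cell$semi_major_um / px
  b_px <- cell$semi_minor_um / px
  half <- ceiling(a_px + extra_halfwidth_px) + 1L
  n <- if (is.null(size)) 2L * half + 1L else as.integer(size)
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  ct <- cos(cell$orientation); st <- sin(cell$orientation)
  u <- (x - cx) * ct + (y - cy) * st
  v <- -(x - cx) * st + (y - cy) * ct
  list(n = n, u = u, v = v, a_px = a_px, b_px = b_px)
}

#' Render a single fluorescence frame and mask for one cell
#'
#' The cell mask is the rasterized projection of the prolate spheroid; the
#' ring channel contains a uniform-intensity bar of length equal to the
#' ground-truth ring diameter, placed across the bud neck at the cell pole
#' and oriented perpendicular to the major axis (the ring viewed edge-on),
#' convolved with the Gaussian PSF, on a constant background with optional
#' noise. Bar edges are rasterized with linear sub-pixel coverage so the
#' analytic full width at half maximum equals the bar length.
#'
#' @param cell A `synthetic_cell`.
#' @param render A [render_config()].
#' @param ring_present If `FALSE`, only background (and noise) is rendered.
#' @param seed Optional integer seed for the noise draw.
#' @param size Optional fixed image side length, px; an error is raised if
#'   the ring does not fit.
#' @return A list with `image` (numeric matrix, a.u.), `mask` (a
#'   [cell_mask()]), and the input `cell`.
#' @export
render_cell_frame <- function(cell, render, ring_present = TRUE, seed = NULL,
                              size = NULL) {
  stopifnot(inherits(cell, "synthetic_cell"), inherits(render,
                                                       "render_config"))
  px <- cell$pixel_size
  d_px <- cell$ring_diameter_true / px
  # margin fits the PSF tails, the ring bar, and the default 30-px
  # half-length measurement profile around the bud-neck pole
  g <- cell_raster_frame(cell,
                         extra_halfwidth_px = max(d_px / 2 +
                                                    6 * render$psf_sigma + 4,
                                                  36),
                         size = size)
  if (!is.null(size) && d_px + 2 > g$n) {
    stop("ring wider than image", call. = FALSE)
  }
  mask <- (g$u / g$a_px)^2 + (g$v / g$b_px)^2 <= 1
  img <- matrix(render$background_level, g$n, g$n)
  if (ring_present) {
    t_px <- render$ring_thickness_px
    cover <- pmin(pmax(d_px / 2 + 0.5 - abs(g$v), 0), 1) *
      pmin(pmax(t_px / 2 + 0.5 - abs(g$u - g$a_px), 0), 1)
    signal <- render$ring_peak_intensity *
      gaussian_blur(cover, render$psf_sigma)
    img <- img + signal
  }
  img <- add_noise(img, render, seed)
  contour <- ellipse_contour(cell, g$n)
  cm <- cell_mask(mask, pixel_size = px, cell_id = cell$cell_id,
                  contour = contour)
  list(image = img, mask = cm, cell = cell)
}

# Analytic contour of the spheroid projection in pixel coordinates of an
# n x n frame centered on the cell.
ellipse_contour <- function(cell, n, n_vertices = 128L) {
  px <- cell$pixel_size
  a_px <- cell$semi_major_um / px
  b_px <- cell$semi_minor_um / px
  cx <- (n + 1) / 2
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ct <- cos(cell$orientation); st <- sin(cell$orientation)
  u <- a_px * cos(phi); v <- b_px * sin(phi)
  cbind(x = cx + u * ct - v * st, y = cx + u * st + v * ct)
}

add_noise <- function(img, render, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(render$shot_noise)) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img))
  }
  if (render$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, render$read_noise_sd)
  }
  img
}

#' Render a confocal-like z-stack of cytoplasmic fluorescence
#'
#' Slices contain the spheroid cross-section at each focal height filled
#' with cytoplasmic signal, blurred in-plane with the Gaussian PSF, on a
#' constant background with optional noise. The slice range covers the cell
#' plus a margin of empty slices on each side.
#'
#' @inheritParams render_cell_frame
#' @return A list with `stack` (3D array row x col x slice, a.u.),
#'   `mask2d` (a [cell_mask()] of the widefield projection), `z_step` (um)
#'   and `pixel_size` (um/px).
#' @export
render_cell_zstack <- function(cell, render, seed = NULL) {
  stopifnot(inherits(cell, "synthetic_cell"), inherits(render,
                                                       "render_config"))
  if (cell$volume_true <= 0) stop("cell has zero volume", call. = FALSE)
  px <- cell$pixel_size
  g <- cell_raster_frame(cell, extra_halfwidth_px = 6 * render$psf_sigma + 4)
  b <- cell$semi_minor_um
  zs <- seq(-(b + 2 * render$z_step), b + 2 * render$z_step,
            by = render$z_step)
  stack <- array(render$background_level, dim = c(g$n, g$n, length(zs)))
  for (k in seq_along(zs)) {
    f2 <- 1 - (zs[k] / b)^2
    if (f2 <= 0) next
    # cross-section of the prolate spheroid at height z
    sect <- (g$u / (g$a_px * sqrt(f2)))^2 + (g$v / (g$b_px * sqrt(f2)))^2 <= 1
    if (!any(sect)) next
    stack[, , k] <- stack[, , k] + render$cytoplasm_intensity *
      gaussian_blur(sect + 0, render$psf_sigma)
  }
  if (!is.null(seed)) set.seed(seed)
  if (render$read_noise_sd > 0) {
    stack <- stack + stats::rnorm(length(stack), 0, render$read_noise_sd)
  }
  mask <- (g$u / g$a_px)^2 + (g$v / g$b_px)^2 <= 1
  cm <- cell_mask(mask, pixel_size = px, cell_id = cell$cell_id,
                  contour = ellipse_contour(cell, g$n))
  list(stack = stack, mask2d = cm, z_step = render$z_step, pixel_size = px)
}

#' Generate a polarization-to-ring timecourse for one cell
#'
#' Emits a frame sequence with a Cdc42-GTP cluster channel whose cortical
#' spot intensity peaks at `cluster_peak_frame` and decays before bud
#' emergence, and a ring channel in which the bud-neck ring appears one
#' frame after the cluster peak and persists for `frame_count_ring` frames.
#' Per-frame ground truth (ring presence, cluster intensity scale, event
#' frames) is returned alongside the images.
#'
#' @inheritParams render_cell_frame
#' @param seed Optional integer seed; the whole sequence is deterministic
#'   under it.
#' @return A list with `frames` (list of per-frame lists: `ring`, `cluster`
#'   images and `mask`), `truth` (per-frame data frame) and `events` (named
#'   list of event frame indices).
#' @export
generate_timecourse <- function(cell, render, seed = NULL) {
  stopifnot(inherits(cell, "synthetic_cell"), inherits(render,
                                                       "render_config"))
  peak <- render$cluster_peak_frame
  bud <- render$bud_emergence_frame
  ring_onset <- peak + 1L
  ring_last <- ring_onset + render$frame_count_ring - 1L
  n_frames <- max(bud, ring_last) + 2L
  px <- cell$pixel_size
  d_px <- cell$ring_diameter_true / px
  dc_px <- cell$cluster_diameter_true / px
  base_seed <- seed %||% 0L
  frames <- vector("list", n_frames)
  cluster_scale <- numeric(n_frames)
  # one frame geometry shared by both channels, wide enough for ring and spot
  g <- cell_raster_frame(cell,
                         extra_halfwidth_px = max(max(d_px, dc_px) / 2 +
                                                    6 * render$psf_sigma + 4,
                                                  36))
  for (f in seq_len(n_frames)) {
    # triangular intensity envelope: rises to the peak, gone by bud emergence
    s <- if (f <= peak) f / peak else max(0, (bud - f) / (bud - peak))
    cluster_scale[f] <- s
    rf <- render_cell_frame(cell, render,
                            ring_present = f >= ring_onset && f <= ring_last,
                            seed = if (is.null(seed)) NULL
                                   else child_seed(base_seed, 2L * f),
                            size = g$n)
    spot <- pmin(pmax(dc_px / 2 + 0.5 -
                        sqrt((g$u - g$a_px)^2 + g$v^2), 0), 1)
    cimg <- render$background_level + s * render$cluster_peak_intensity *
      gaussian_blur(spot, render$psf_sigma)
    cimg <- add_noise(cimg, render,
                      seed = if (is.null(seed)) NULL
                             else child_seed(base_seed, 2L * f + 1L))
    frames[[f]] <- list(ring = rf$image, cluster = cimg, mask = rf$mask)
  }
  truth <- data.frame(frame = seq_len(n_frames),
                      ring_present = seq_len(n_frames) >= ring_onset &
                        seq_len(n_frames) <= ring_last,
                      ring_d_true_um = cell$ring_diameter_true,
                      cluster_scale = cluster_scale)
  list(frames = frames, truth = truth,
       events = list(cluster_peak_frame = peak, bud_emergence_frame = bud,
                     ring_onset_frame = ring_onset,
                     ring_last_frame = ring_last))
}

#' Generate a replicative-aging track of one mother cell
#'
#' Mother volume at cytokinesis increases with generation number by a
#' configurable per-generation growth rule; the ring diameter per generation
#' follows `d_norm = V_norm^beta` with optional multiplicative noise.
#' Generation 1 defines the normalization (first bud event).
#'
#' @param cell A `synthetic_cell` (generation-1 state).
#' @param n_generations Number of generations (>= 1).
#' @param volume_growth_rate Per-generation fractional increase of mother
#'   volume (linear rule: `V(g) = V(1) * (1 + rate * (g - 1))`).
#' @param beta Aging scaling exponent relating normalized diameter to
#'   normalized volume.
#' @param noise_cv CV of multiplicative lognormal diameter noise.
#' @param daughter_fraction Daughter volume as a fraction of the
#'   generation-1 mother volume.
#' @param seed Optional integer seed.
#' @return A list of per-generation `synthetic_cell` objects.
#' @export
generate_aging_track <- function(cell, n_generations,
                                 volume_growth_rate = 0.07,
                                 beta = 0.15, noise_cv = 0,
                                 daughter_fraction = 0.6, seed = NULL) {
  stopifnot(inherits(cell, "synthetic_cell"))
  n_generations <- check_count(n_generations, "n_generations")
  check_nonnegative(volume_growth_rate, "volume_growth_rate")
  check_nonnegative(noise_cv, "noise_cv")
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  v1 <- cell$volume_true
  d1 <- cell$ring_diameter_true
  asp <- cell$semi_major_um / cell$semi_minor_um
  lapply(seq_len(n_generations), function(g) {
    vg <- v1 * (1 + volume_growth_rate * (g - 1))
    noise <- if (noise_cv > 0) exp(stats::rnorm(1, 0, sdlog)) else 1
    dg <- d1 * (vg / v1)^beta * noise
    out <- make_synthetic_cell(vg, asp, dg,
                               cell$cluster_diameter_true *
                                 (vg / v1)^(1 / 3),
                               cell$orientation, cell$pixel_size,
                               cell_id = cell$cell_id, generation = g)
    out$daughter_volume <- daughter_fraction * v1 *
      (1 + 0.02 * (g - 1))
    out
  })
}

#' Per-generation aging records of a track
#'
#' @param track List of per-generation `synthetic_cell` objects from
#'   [generate_aging_track()].
#' @return A data frame with columns `cell_id`, `generation`,
#'   `volume_at_cytokinesis` (fL), `daughter_volume` (fL), `diameter` (um).
#' @export
aging_records <- function(track) {
  data.frame(cell_id = vapply(track, `[[`, "", "cell_id"),
             generation = vapply(track, `[[`, 1L, "generation"),
             volume_at_cytokinesis = vapply(track, `[[`, 0, "volume_true"),
             daughter_volume = vapply(track, function(c)
               c$daughter_volume %||% NA_real_, 0),
             diameter = vapply(track, `[[`, 0, "ring_diameter_true"),
             stringsAsFactors = FALSE)
}
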