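# Pipeline orchestration: simulate -> measure -> aggregate -> fit, with
# stable file contracts (TIFF frames, CSV tables, YAML configs, JSON fit
# reports) and all randomness funneled through explicit seeds.

#' Simulate a full synthetic scene
#'
#' Generates a population and renders each cell for a number of frames
#' (independent noise per frame, constant geometry), yielding the input the
#' measurement pipeline consumes in place of raw microscopy data.
#'
#' @param pop A [population_config()].
#' @param render A [render_config()].
#' @param frames_per_cell Number of rendered frames per cell (default: the
#'   render config's `frame_count_ring`).
#' @return An object of class `scene`: a list with `cells` (each holding the
#'   ground-truth `cell`, the `mask`, and a list of `frames`), `truth`
#'   (ground-truth table), `pixel_size`, and the two configs.
#' @export
simulate_scene <- function(pop, render, frames_per_cell = NULL) {
  stopifnot(inherits(pop, "population_config"),
            inherits(render, "render_config"))
  nf <- frames_per_cell %||% render$frame_count_ring
  nf <- check_count(nf, "frames_per_cell")
  cells <- generate_population(pop)
  rendered <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    frame_seed_base <- child_seed(pop$seed, 100000L + i)
    first <- render_cell_frame(cell, render, seed = child_seed(
      frame_seed_base, 1L))
    frames <- vector("list", nf)
    frames[[1L]] <- first$image
    if (nf > 1L) for (f in 2:nf) {
      frames[[f]] <- render_cell_frame(cell, render,
                                       seed = child_seed(frame_seed_base,
                                                         f))$image
    }
    list(cell = cell, mask = first$mask, frames = frames)
  })
  structure(list(cells = rendered, truth = population_truth(cells),
                 pixel_size = pop$pixel_size, pop_config = pop,
                 render_config = render),
            class = "scene")
}

#' Measure every cell of a scene
#'
#' Runs the per-frame measurement (ring detection, line profile, gliding
#' average and background subtraction, full width at half maximum,
#' integrated intensity) and the mask morphometry (revolution volume,
#' major-axis length, elongation) for every cell, then aggregates each
#' track into per-cell medians. Rejection reasons (too few valid ring
#' frames) are recorded in the `accepted` flag.
#'
#' @param scene A `scene` from [simulate_scene()] or [read_scene()].
#' @param threshold Ring binarization threshold, a.u.; a required analysis
#'   parameter, set per dataset.
#' @param min_area Minimal ring component area, px.
#' @param half_length Profile half length, px (30; 60 for large-cell
#'   strains).
#' @param avg_width Perpendicular averaging width, px.
#' @param min_frames Minimal number of valid ring frames for acceptance.
#' @param exclude Character vector of cell ids to exclude (the per-cell
#'   rejection list).
#' @return A data frame with one row per cell: measurement summaries, the
#'   geometry columns, the acceptance flag, and (for synthetic scenes) the
#'   ground-truth columns `true_volume_fL`, `true_d_um`.
#' @export
run_measure <- function(scene, threshold, min_area = 10L, half_length = 30L,
                        avg_width = 10L, min_frames = 5L,
                        exclude = character()) {
  stopifnot(inherits(scene, "scene"))
  check_positive(threshold, "threshold")
  px <- scene$pixel_size
  rows <- lapply(scene$cells, function(sc) {
    id <- sc$cell$cell_id
    if (id %in% exclude) return(NULL)
    geom <- cell_geometry(sc$mask)
    per_frame <- do.call(rbind, lapply(seq_along(sc$frames), function(f) {
      measure_ring(sc$frames[[f]], threshold, px, min_area = min_area,
                   half_length = half_length, avg_width = avg_width,
                   frame = f)
    }))
    per_frame$volume_fL <- geom$volume_fL
    per_frame$length_um <- geom$length_um
    summ <- aggregate_track(per_frame, min_frames = min_frames,
                            cell_id = id)
    summ$elongation <- geom$elongation
    summ$true_volume_fL <- sc$cell$volume_true
    summ$true_d_um <- sc$cell$ring_diameter_true
    summ
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no cells to measure in the scene", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Fit the scaling models to a per-cell summary table
#'
#' The statistics layer of the pipeline: power-law fit of median ring
#' diameter against median cell volume with a bootstrap confidence interval
#' for the exponent, comparison against linear and logarithmic models,
#' binned means, and (optionally) deviation ratios against a reference fit.
#'
#' @param summary Per-cell table from [run_measure()] (columns
#'   `median_d_um`, `median_volume_fL`, `accepted`), or any data frame with
#'   those columns.
#' @param n_boot Bootstrap resamples for the exponent CI (50,000 by
#'   convention).
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap; recorded in the report.
#' @param n_bins Number of equally spaced log10-volume bins for the binned
#'   means.
#' @param reference Optional reference `power_law_fit` for deviation
#'   ratios.
#' @param out_json Optional path; if given, the report is written as JSON.
#' @return A list (class `fit_report`): `power` fit, `comparison`,
#'   `binned`, `deviation` (median ratio and per-cell ratios, when a
#'   reference is given), `n_cells`, `seed`.
#' @export
run_fit <- function(summary, n_boot = 50000L, level = 0.95, seed = 1L,
                    n_bins = 8L, reference = NULL, out_json = NULL) {
  stopifnot(is.data.frame(summary),
            all(c("median_d_um", "median_volume_fL") %in% names(summary)))
  acc <- if ("accepted" %in% names(summary)) summary[summary$accepted, ]
         else summary
  if (nrow(acc) < 3L) {
    stop("insufficient data: need at least 3 accepted cells", call. = FALSE)
  }
  d <- acc$median_d_um; V <- acc$median_volume_fL
  pw <- fit_power_law(d, V, n_boot = n_boot, level = level, seed = seed)
  cmp <- compare_models(d, V)
  edges <- 10^seq(log10(min(V)) - 1e-9, log10(max(V)) + 1e-9,
                  length.out = n_bins + 1L)
  binned <- binned_means(V, d, edges)
  deviation <- NULL
  if (!is.null(reference)) {
    ratios <- deviation_ratio(d, V, reference)
    deviation <- list(median_ratio = stats::median(ratios), ratios = ratios)
  }
  report <- structure(list(power = pw, comparison = cmp, binned = binned,
                           deviation = deviation, n_cells = nrow(acc),
                           seed = as.integer(seed)),
                      class = "fit_report")
  if (!is.null(out_json)) {
    jsonlite::write_json(fit_report_json(report), out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Plain-list view of a fit report for JSON serialization.
fit_report_json <- function(report) {
  list(power = list(exponent = report$power$slope,
                    intercept_log10 = report$power$intercept,
                    prefactor = 10^report$power$intercept,
                    ci_lo = report$power$ci_lo, ci_hi = report$power$ci_hi,
                    n_boot = report$power$n_boot,
                    ssr_linear_space = report$power$ssr_linear_space,
                    ssr_log_space = report$power$ssr_log_space),
       models = report$comparison$models,
       winner = report$comparison$winner,
       binned = report$binned,
       deviation_median_ratio = report$deviation$median_ratio,
       n_cells = report$n_cells,
       seed = report$seed)
}

#' @export
print.fit_report <- function(x, ...) {
  print(x$power)
  print(x$comparison)
  if (!is.null(x$deviation)) {
    cat(sprintf("Median deviation ratio vs reference fit: %.3f\n",
                x$deviation$median_ratio))
  }
  invisible(x)
}

#' Write a scene to disk
#'
#' File contract for simulated scenes: one multi-page 16-bit TIFF per cell
#' (ring channel), one TIFF mask per cell, a ground-truth CSV, and the
#' scene configuration as YAML. Intensities are stored as counts out of
#' 65535.
#'
#' @param scene A `scene`.
#' @param dir Output directory (created if missing).
#' @param max_count Intensity mapped to the 16-bit full scale.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, max_count = 65535) {
  stopifnot(inherits(scene, "scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sc in scene$cells) {
    id <- sc$cell$cell_id
    tiff::writeTIFF(lapply(sc$frames, function(f) {
      pmin(pmax(f / max_count, 0), 1)
    }), file.path(dir, paste0(id, "_ring.tif")), bits.per.sample = 16L)
    tiff::writeTIFF(sc$mask$mask * 1.0,
                    file.path(dir, paste0(id, "_mask.tif")),
                    bits.per.sample = 16L)
  }
  utils::write.csv(scene$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- list(pixel_size = scene$pixel_size,
              population = unclass(scene$pop_config),
              render = unclass(scene$render_config),
              max_count = max_count,
              schema_version = 1L)
  yaml::write_yaml(cfg, file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' Read a scene from disk
#'
#' Counterpart of [write_scene()]; restores images to a.u., masks, the
#' ground-truth table and the configuration.
#'
#' @param dir Scene directory.
#' @return A `scene`.
#' @export
read_scene <- function(dir) {
  cfg_path <- file.path(dir, "scene.yaml")
  if (!file.exists(cfg_path)) {
    stop("not a scene directory (missing scene.yaml): ", dir, call. = FALSE)
  }
  cfg <- yaml::read_yaml(cfg_path)
  truth <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                           stringsAsFactors = FALSE)
  px <- cfg$pixel_size
  cells <- lapply(truth$cell_id, function(id) {
    pages <- tiff::readTIFF(file.path(dir, paste0(id, "_ring.tif")),
                            all = TRUE)
    frames <- lapply(pages, function(p) p * cfg$max_count)
    m <- tiff::readTIFF(file.path(dir, paste0(id, "_mask.tif"))) > 0.5
    row <- truth[truth$cell_id == id, ]
    cell <- make_synthetic_cell(row$volume_true_fL, 1, row$d_true_um,
                                row$cluster_d_true_um, 0, px, id,
                                generation = row$generation)
    cell$length_true <- row$length_true_um
    list(cell = cell, mask = cell_mask(m, pixel_size = px, cell_id = id),
         frames = frames)
  })
  pop <- do.call(population_config, cfg$population)
  render <- do.call(render_config, cfg$render)
  structure(list(cells = cells, truth = truth, pixel_size = px,
                 pop_config = pop, render_config = render),
            class = "scene")
}
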