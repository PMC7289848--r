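#' Summarize a per-frame cell track
#'
#' Turns per-frame ring and geometry measurements for one cell into the
#' per-cell summary the scaling analysis consumes: medians over the frames
#' with a valid ring detection only, and an acceptance flag requiring at
#' least `min_frames` valid ring frames. A track with no valid frames yields
#' a rejected summary, not an error.
#'
#' @param track Data frame with one row per frame and columns `frame`,
#'   `d_um`, `valid`, and optionally `intensity_au`, `volume_fL`,
#'   `length_um`.
#' @param min_frames Minimal number of valid ring frames for acceptance.
#' @param cell_id Cell identifier carried into the summary.
#' @return A one-row data frame: `cell_id`, `median_d_um`,
#'   `median_volume_fL`, `median_length_um`, `median_intensity_au`,
#'   `n_ring_frames`, `accepted`.
#' @export
aggregate_track <- function(track, min_frames = 5L, cell_id = "cell") {
  stopifnot(is.data.frame(track), nrow(track) >= 1L,
            all(c("frame", "d_um", "valid") %in% names(track)))
  if (is.unsorted(track$frame, strictly = TRUE)) {
    stop("frames must be strictly increasing", call. = FALSE)
  }
  ok <- which(track$valid)
  med <- function(col) {
    if (length(ok) == 0L || is.null(track[[col]])) NA_real_
    else stats::median(track[[col]][ok])
  }
  data.frame(cell_id = cell_id,
             median_d_um = med("d_um"),
             median_volume_fL = med("volume_fL"),
             median_length_um = med("length_um"),
             median_intensity_au = med("intensity_au"),
             n_ring_frames = length(ok),
             accepted = length(ok) >= min_frames,
             stringsAsFactors = FALSE)
}

#' Normalize aging records to the first division
#'
#' Adds `d_norm` and `V_norm` columns: diameter normalized to the diameter
#' at the first bud event and mother volume normalized to the volume at the
#' first division (generation 1), per cell.
#'
#' @param records Data frame with columns `generation`,
#'   `volume_at_cytokinesis`, `diameter`, and optionally `cell_id`.
#' @return The records with `d_norm` and `V_norm` columns; generation 1 has
#'   `d_norm = V_norm = 1` by construction.
#' @export
normalize_aging <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("generation", "volume_at_cytokinesis", "diameter") %in%
                  names(records)))
  ids <- records$cell_id %||% rep("cell", nrow(records))
  out <- lapply(split(records, ids), function(r) {
    first <- which(r$generation == 1L)
    if (length(first) != 1L) {
      stop("each cell needs exactly one generation-1 record", call. = FALSE)
    }
    r$V_norm <- r$volume_at_cytokinesis / r$volume_at_cytokinesis[first]
    r$d_norm <- r$diameter / r$diameter[first]
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Deviation of measured from expected ring diameter
#'
#' The mutant-comparison statistic: the ratio of the measured ring diameter
#' to the diameter predicted by a reference power-law fit at the same cell
#' volume, `d / (10^intercept * V^slope)`. A cell lying exactly on the
#' reference fit scores 1.
#'
#' @param d_um Measured diameters, um.
#' @param volume_fL Cell volumes, fL (positive).
#' @param reference A `power_law_fit` from [fit_power_law()].
#' @return Vector of dimensionless ratios.
#' @export
deviation_ratio <- function(d_um, volume_fL, reference) {
  stopifnot(inherits(reference, "power_law_fit"))
  if (any(!is.finite(volume_fL) | volume_fL <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  d_um / (10^reference$intercept * volume_fL^reference$slope)
}
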