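#' Intracellular voltage trace
#'
#' @param samples Voltage samples (mV), uniformly sampled.
#' @param sample_rate Sampling rate (Hz), 30 kHz in the recordings this
#'   mirrors.
#' @param t0 Time of the first sample (s); traces typically start one
#'   inter-stimulus gap before the first presentation so every presentation
#'   has a baseline window.
#' @return An object of class `intracellular_trace`.
#' @export
intracellular_trace <- function(samples, sample_rate = 30000, t0 = 0) {
  stop_if_not(is.numeric(samples) && all(is.finite(samples)),
              "samples must be finite numeric")
  stop_if_not(is_number(sample_rate) && sample_rate > 0,
              "sample_rate must be positive")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 t0 = t0),
            class = "intracellular_trace")
}

trace_window_mean <- function(trace, from, to) {
  w <- sample_window(from, to, trace$t0, trace$sample_rate)
  stop_if_not(w[1] >= 1 && w[2] <= length(trace$samples) && w[2] >= w[1],
              "window [%g, %g] s lies outside the trace", from, to)
  mean(trace$samples[w[1]:w[2]])
}

#' Baseline-referenced response to one stimulus presentation
#'
#' Mean membrane voltage during the presentation window minus the mean over
#' the baseline window (by convention, the inter-stimulus gap immediately
#' preceding the presentation).
#'
#' @param trace An [intracellular_trace()].
#' @param window Numeric `(onset, offset)` of the presentation (s).
#' @param baseline_window Numeric `(from, to)` of the baseline (s).
#' @return Depolarisation in mV (positive = depolarised relative to
#'   baseline).
#' @export
location_response <- function(trace, window, baseline_window) {
  stopifnot(inherits(trace, "intracellular_trace"))
  stop_if_not(window[2] > window[1] && baseline_window[2] > baseline_window[1],
              "windows must have positive duration")
  trace_window_mean(trace, window[1], window[2]) -
    trace_window_mean(trace, baseline_window[1], baseline_window[2])
}

#' Receptive-field map from a trace and a grid schedule
#'
#' Computes [location_response()] for every scheduled presentation and
#' arranges the responses on the stimulus grid. The baseline for each
#' presentation is the gap of length `attr(schedule, "gap_duration")`
#' immediately before its onset, so the trace must start at least one gap
#' before the first onset.
#'
#' @param trace An [intracellular_trace()].
#' @param schedule A [make_grid_schedule()].
#' @return An object of class `rf_map`: the response matrix (`grid_shape`),
#'   with the schedule geometry attached as attributes.
#' @export
build_rf_map <- function(trace, schedule) {
  stopifnot(inherits(trace, "intracellular_trace"),
            inherits(schedule, "grid_schedule"))
  gap <- attr(schedule, "gap_duration")
  t_end <- trace$t0 + length(trace$samples) / trace$sample_rate
  stop_if_not(trace$t0 <= min(schedule$onset) - gap &&
                t_end >= max(schedule$offset),
              "trace [%g, %g] s does not span the schedule (incl. baselines)",
              trace$t0, t_end)
  shp <- attr(schedule, "grid_shape")
  m <- matrix(NA_real_, shp[1], shp[2])
  for (i in seq_len(nrow(schedule))) {
    m[schedule$row[i], schedule$col[i]] <- location_response(
      trace,
      c(schedule$onset[i], schedule$offset[i]),
      c(schedule$onset[i] - gap, schedule$onset[i]))
  }
  structure(m, class = c("rf_map", "matrix"),
            grid_shape = shp, square_size = attr(schedule, "square_size"))
}

#' Smooth and upsample a receptive-field map for display
#'
#' Gaussian smoothing (sd = `kernel_sd` cells on the original grid) followed
#' by separable bicubic-spline upsampling by `upsample`. This is a display
#' aid; centroids and tuning curves are computed on the raw grid.
#'
#' @param map Numeric matrix (an `rf_map` or plain matrix).
#' @param upsample Integer upsampling factor (default 10).
#' @param kernel_sd Gaussian kernel sd in grid cells (default 1).
#' @return Matrix of size `(nrow-1)*upsample + 1` by `(ncol-1)*upsample + 1`.
#' @export
interpolate_smooth <- function(map, upsample = 10, kernel_sd = 1) {
  stop_if_not(is.matrix(map) && all(is.finite(map)), "map must be finite")
  sm <- gaussian_smooth(unclass(map), sd = kernel_sd)
  nr <- nrow(map); nc <- ncol(map)
  if (nr < 2 || nc < 2 || upsample == 1) return(sm)
  interp2_spline(seq_len(nc), seq_len(nr), sm,
                 seq(1, nc, length.out = (nc - 1) * upsample + 1),
                 seq(1, nr, length.out = (nr - 1) * upsample + 1))
}

#' Normalise a cell's maps to its maximum response across trials
#'
#' All maps from one cell (across stimulus conditions/trials) are divided by
#' the single largest response among them, so the strongest condition peaks
#' at 1 and relative amplitudes between conditions are preserved.
#'
#' @param maps Named list of response matrices for one cell.
#' @return List of normalised maps (attributes preserved).
#' @export
normalise_maps <- function(maps) {
  stop_if_not(is.list(maps) && length(maps) >= 1, "maps must be a list")
  mx <- max(vapply(maps, max, numeric(1)))
  stop_if_not(mx > 0, "all responses are non-positive; cannot normalise")
  lapply(maps, function(m) m / mx)
}

#' Receptive-field centroid from a thresholded binary mask
#'
#' The map is thresholded at `threshold` of its maximum; the centroid is
#' the unweighted centre of mass of the super-threshold support (set
#' `weighted = TRUE` for a response-weighted centroid over the same
#' support). Coordinates are returned as fractional `(row, col)` grid
#' indices and, if the map carries a `square_size`, as `(azimuth,
#' elevation)` in degrees.
#'
#' @param map Response matrix.
#' @param threshold Fraction of the map maximum (default 0.30).
#' @param weighted Response-weighted centroid instead of binary (default
#'   FALSE).
#' @return List with `row`, `col` (fractional grid indices) and, when the
#'   geometry is known, `azimuth`, `elevation` (deg).
#' @export
rf_centroid <- function(map, threshold = 0.30, weighted = FALSE) {
  stop_if_not(is.matrix(map), "map must be a matrix")
  mx <- max(map)
  stop_if_not(is.finite(mx) && mx > 0, "map has no positive response")
  mask <- map >= threshold * mx
  stop_if_not(any(mask), "no super-threshold pixels")
  w <- if (weighted) map * mask else mask * 1
  rows <- row(map); cols <- col(map)
  ctr <- list(row = sum(rows * w) / sum(w), col = sum(cols * w) / sum(w))
  sz <- attr(map, "square_size"); shp <- dim(map)
  if (!is.null(sz)) {
    ctr$azimuth <- (ctr$col - (shp[2] + 1) / 2) * sz
    ctr$elevation <- ((shp[1] + 1) / 2 - ctr$row) * sz
  }
  ctr
}

# Integer-shift a matrix, padding with NA.
shift_map <- function(m, dr, dc) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Align maps on their non-polarised centroids and average across cells
#'
#' Each cell's maps are translated so that the centroid of that cell's
#' non-polarised (reference) map sits at the grid centre, then averaged
#' elementwise across cells (ignoring cells with no data at a given cell
#' after shifting). Shifts are rounded to whole grid cells.
#'
#' @param maps List (one per cell) of response matrices for a common
#'   condition.
#' @param reference_centroids List (one per cell) of centroids from each
#'   cell's non-polarised map, as returned by [rf_centroid()].
#' @return The aligned mean map (matrix).
#' @export
align_and_average <- function(maps, reference_centroids) {
  stop_if_not(length(maps) >= 1 &&
                length(maps) == length(reference_centroids),
              "need one reference centroid per map")
  shp <- dim(maps[[1]])
  centre <- (shp + 1) / 2
  shifted <- Map(function(m, ctr) {
    stop_if_not(!is.null(ctr$row) && !is.null(ctr$col),
                "reference centroid missing for a cell")
    shift_map(unclass(m), round(centre[1] - ctr$row),
              round(centre[2] - ctr$col))
  }, maps, reference_centroids)
  out <- apply(simplify2array(shifted), c(1, 2), mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Polarisation tuning curve from maps by stimulus condition
#'
#' The tuning value for each angle-of-polarisation condition is the maximum
#' of that condition's (normalised) receptive-field map; the non-polarised
#' condition, when present, is carried as a reference level.
#'
#' @param maps Named list of maps; polarised conditions named by their AoP
#'   in degrees (e.g. `"0"`, `"45"`), the non-polarised condition `"NP"`.
#' @return An object of class `pol_tuning_curve`: data.frame `aop`,
#'   `response`, plus attribute `np_response` (or `NA`).
#' @export
polarisation_tuning <- function(maps) {
  nm <- names(maps)
  stop_if_not(!is.null(nm) && all(nzchar(nm)), "maps must be named")
  pol <- nm[nm != "NP"]
  stop_if_not(length(pol) >= 2, "need >= 2 AoP conditions")
  aop <- suppressWarnings(as.numeric(pol))
  stop_if_not(all(is.finite(aop)), "polarised conditions must be named by AoP")
  curve <- data.frame(aop = aop %% 180,
                      response = vapply(maps[pol], max, numeric(1)))
  curve <- curve[order(curve$aop), ]
  rownames(curve) <- NULL
  structure(curve, class = c("pol_tuning_curve", "data.frame"),
            np_response = if ("NP" %in% nm) max(maps[["NP"]]) else NA_real_)
}

#' Polarisation-sensitivity ratio of a tuning curve
#'
#' Ratio of the maximum to the minimum of the polarisation tuning curve;
#' 1 for a polarisation-blind cell, ~2 for typical polarisation-sensitive
#' butterfly photoreceptors.
#'
#' @param curve A [polarisation_tuning()] result (or data.frame with a
#'   `response` column).
#' @return PS ratio (>= 1).
#' @export
ps_ratio <- function(curve) {
  r <- curve$response
  stop_if_not(min(r) > 0, "tuning minimum must be positive")
  max(r) / min(r)
}
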