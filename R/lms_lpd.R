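#' Spike train recorded during circular-dot stimulation
#'
#' @param spike_times Spike times (s), strictly increasing.
#' @param unit Unit label.
#' @param direction Dot rotation direction, `"CW"` or `"CCW"`.
#' @param condition Free-form condition label (contrast, AoP, ...).
#' @param location Stimulus location `(azimuth, elevation)` in deg.
#' @param animal Animal identifier (used by the tuning-curve aggregators).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, unit = "unit1",
                        direction = c("CW", "CCW"), condition = "",
                        location = c(0, 0), animal = "animal1") {
  direction <- match.arg(direction)
  stop_if_not(is.numeric(spike_times) && !is.unsorted(spike_times, strictly = TRUE),
              "spike_times must be strictly increasing")
  structure(list(spike_times = as.numeric(spike_times), unit = unit,
                 direction = direction, condition = condition,
                 location = location, animal = animal),
            class = "spike_train")
}

#' Instantaneous motion direction at each spike time
#'
#' Evaluates the dot's motion direction theta(t) at every spike time
#' (spike-triggered direction). Spikes outside the trajectory span are
#' dropped; the number dropped is attached as an attribute.
#'
#' @param train A [spike_train()].
#' @param traj A [make_dot_trajectory()] for the same rotation direction.
#' @return Vector of motion directions (deg in \[0, 360)), with attribute
#'   `n_dropped`.
#' @export
spike_motion_directions <- function(train, traj) {
  stopifnot(inherits(train, "spike_train"), inherits(traj, "dot_trajectory"))
  keep <- train$spike_times >= 0 & train$spike_times <= traj$duration
  th <- trajectory_angles(traj, train$spike_times[keep])$motion_direction
  attr(th, "n_dropped") <- sum(!keep)
  th
}

#' Circular mean and resultant length of a set of angles
#'
#' Direction of the sum of unit vectors; `R = |sum| / n` measures
#' concentration (1 = all angles identical, 0 = balanced/antipodal, in
#' which case the mean is undefined and returned as `NA`).
#'
#' @param angles Angles in degrees (non-empty).
#' @param r_tol Resultant lengths below this are treated as 0 (undefined
#'   mean).
#' @return List with `mean` (deg in \[0, 360), `NA` if undefined) and `R`.
#' @export
circular_mean <- function(angles, r_tol = 1e-12) {
  stop_if_not(length(angles) >= 1, "angles must be non-empty")
  cx <- mean(cosd(angles)); sx <- mean(sind(angles))
  R <- sqrt(cx^2 + sx^2)
  list(mean = if (R < r_tol) NA_real_ else wrap360(atan2d(sx, cx)), R = R)
}

#' Latency-corrected local preferred direction
#'
#' The response latency delays spikes, rotating the apparent preferred
#' direction by +omega*latency for CW dots and -omega*latency for CCW dots.
#' The resultant of the two single-direction estimates cancels this phase
#' lag: the corrected LPD is the direction of the sum of the two unit
#' vectors.
#'
#' @param lpd_cw,lpd_ccw Single-direction LPD estimates (deg).
#' @return Corrected LPD (deg in \[0, 360)); `NA` with a warning if the two
#'   estimates are antipodal.
#' @export
latency_corrected_lpd <- function(lpd_cw, lpd_ccw) {
  stop_if_not(is.finite(lpd_cw) && is.finite(lpd_ccw),
              "both LPD estimates must be defined")
  cx <- cosd(lpd_cw) + cosd(lpd_ccw)
  sx <- sind(lpd_cw) + sind(lpd_ccw)
  if (sqrt(cx^2 + sx^2) < 1e-9) {
    warning("antipodal LPD estimates: corrected LPD undefined", call. = FALSE)
    return(NA_real_)
  }
  wrap360(atan2d(sx, cx))
}

#' Spike rate within an angular sector of motion directions
#'
#' Counts spikes whose instantaneous motion direction lies within
#' `halfwidth` deg of `centre`, divided by the total time the dot's motion
#' direction dwells in that sector. For a constant-speed circular
#' trajectory the dwell time is `duration * 2 * halfwidth / 360`.
#'
#' @param train A [spike_train()].
#' @param traj The matching [make_dot_trajectory()].
#' @param centre Sector centre in motion-direction space (deg).
#' @param halfwidth Sector half-width (deg, default 45).
#' @return Spike rate in spikes/s.
#' @export
sector_rate <- function(train, traj, centre, halfwidth = 45) {
  stop_if_not(halfwidth > 0 && halfwidth <= 180, "halfwidth must be in (0, 180]")
  dwell <- traj$duration * min(2 * halfwidth, 360) / 360
  stop_if_not(dwell > 0, "sector dwell time is zero")
  th <- spike_motion_directions(train, traj)
  n <- sum(abs(wrap180(th - centre)) <= halfwidth)
  n / dwell
}

#' Local motion sensitivity from the four sector rates
#'
#' Mean over the two rotation directions of the difference between the
#' spike rate within 45 deg of the LPD (`a`) and within 45 deg of the
#' anti-LPD (`b`):
#' `LMS = ((a_cw - b_cw) + (a_ccw - b_ccw)) / 2`.
#'
#' @param a_cw,a_ccw Preferred-sector rates for CW and CCW dots (spikes/s).
#' @param b_cw,b_ccw Anti-preferred-sector rates (spikes/s).
#' @return LMS in spikes/s.
#' @export
lms <- function(a_cw, a_ccw, b_cw, b_ccw) {
  stop_if_not(all(c(a_cw, a_ccw, b_cw, b_ccw) >= 0),
              "sector rates must be non-negative")
  ((a_cw - b_cw) + (a_ccw - b_ccw)) / 2
}

#' Local preferred direction and motion sensitivity at one location
#'
#' Composes the full fast-protocol analysis: single-direction LPDs as
#' circular means of spike-triggered motion directions, the
#' latency-corrected LPD as their resultant, and the LMS from preferred and
#' anti-preferred sector rates of both rotation directions.
#'
#' @param train_cw,train_ccw [spike_train()]s for CW and CCW rotations.
#' @param traj_cw,traj_ccw The matching trajectories.
#' @param halfwidth Sector half-width (deg, default 45).
#' @return An object of class `local_motion_estimate`: `lpd`, `lpd_cw`,
#'   `lpd_ccw` (deg), `lms` (spikes/s), `resultant_length`, the four sector
#'   rates, and spike counts.
#' @export
estimate_local_motion <- function(train_cw, train_ccw, traj_cw, traj_ccw,
                                  halfwidth = 45) {
  stop_if_not(train_cw$direction == "CW" && traj_cw$direction == "CW",
              "train_cw/traj_cw must be clockwise")
  stop_if_not(train_ccw$direction == "CCW" && traj_ccw$direction == "CCW",
              "train_ccw/traj_ccw must be counter-clockwise")
  th_cw <- spike_motion_directions(train_cw, traj_cw)
  th_ccw <- spike_motion_directions(train_ccw, traj_ccw)
  stop_if_not(length(th_cw) > 0 && length(th_ccw) > 0,
              "no spikes within the trajectory span")
  m_cw <- circular_mean(th_cw)
  m_ccw <- circular_mean(th_ccw)
  lpd <- latency_corrected_lpd(m_cw$mean, m_ccw$mean)
  a_cw <- sector_rate(train_cw, traj_cw, lpd, halfwidth)
  a_ccw <- sector_rate(train_ccw, traj_ccw, lpd, halfwidth)
  b_cw <- sector_rate(train_cw, traj_cw, lpd + 180, halfwidth)
  b_ccw <- sector_rate(train_ccw, traj_ccw, lpd + 180, halfwidth)
  structure(list(lpd = lpd, lpd_cw = m_cw$mean, lpd_ccw = m_ccw$mean,
                 lms = lms(a_cw, a_ccw, b_cw, b_ccw),
                 resultant_length = mean(c(m_cw$R, m_ccw$R)),
                 a_cw = a_cw, a_ccw = a_ccw, b_cw = b_cw, b_ccw = b_ccw,
                 n_spikes_cw = length(th_cw), n_spikes_ccw = length(th_ccw)),
            class = "local_motion_estimate")
}

# Within-animal trial averaging before cross-animal mean +/- sd.
aggregate_levels <- function(df, level_col) {
  stop_if_not(all(c(level_col, "animal", "lms") %in% names(df)),
              "need columns %s, animal, lms", level_col)
  per_animal <- stats::aggregate(df$lms,
    by = list(level = df[[level_col]], animal = df$animal), FUN = mean)
  out <- do.call(rbind, lapply(split(per_animal, per_animal$level), function(g) {
    data.frame(level = g$level[1], lms_mean = mean(g$x),
               lms_sd = if (nrow(g) > 1) stats::sd(g$x) else NA_real_,
               n_animals = nrow(g))
  }))
  out <- out[order(out$level), ]
  rownames(out) <- NULL
  out
}

#' Contrast tuning curve of local motion sensitivity
#'
#' LMS values are first averaged over trials within each animal, then
#' averaged across animals (mean +/- 1 sd), per contrast level. A
#' correlator-type motion pathway yields a V-shaped curve with its minimum
#' at contrast 0.
#'
#' @param df data.frame with columns `contrast`, `animal`, `lms` (one row
#'   per trial).
#' @return data.frame `level`, `lms_mean`, `lms_sd`, `n_animals`, ordered
#'   by contrast.
#' @export
contrast_tuning <- function(df) {
  out <- aggregate_levels(df, "contrast")
  names(out)[1] <- "contrast"
  out
}

#' AoP tuning curve of local motion sensitivity
#'
#' As [contrast_tuning()], per angle-of-polarisation condition (deg, or
#' `"NP"` for the non-polarised reference). Polarisation-blind neurons give
#' a flat curve.
#'
#' @param df data.frame with columns `aop`, `animal`, `lms`.
#' @return data.frame `aop`, `lms_mean`, `lms_sd`, `n_animals`.
#' @export
aop_tuning <- function(df) {
  out <- aggregate_levels(df, "aop")
  names(out)[1] <- "aop"
  out
}

#' Vector-field receptive field on an azimuth/elevation grid
#'
#' @param azimuth,elevation Strictly increasing sample grids (deg; azimuth
#'   positive = right visual field, elevation positive = dorsal).
#' @param lpd,lms Matrices `length(elevation) x length(azimuth)` of local
#'   preferred directions (deg) and motion sensitivities (spikes/s or
#'   normalised).
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(azimuth, elevation, lpd, lms) {
  stop_if_not(is.matrix(lpd) && is.matrix(lms) &&
                all(dim(lpd) == c(length(elevation), length(azimuth))) &&
                all(dim(lms) == dim(lpd)),
              "lpd/lms must be length(elevation) x length(azimuth)")
  structure(list(azimuth = azimuth, elevation = elevation,
                 lpd = lpd, lms = lms),
            class = "vector_field")
}

#' Interpolate a vector field onto a finer angular grid
#'
#' The field is decomposed into Cartesian components
#' `u = lms cos(lpd)`, `v = lms sin(lpd)`, each interpolated with a
#' separable bicubic spline, then re-expressed as direction and magnitude.
#' Sampled nodes are reproduced exactly.
#'
#' @param field A [vector_field()] with at least 4 x 4 nodes.
#' @param step Output grid increment (deg, default 15).
#' @return Interpolated [vector_field()].
#' @export
interpolate_vector_field <- function(field, step = 15) {
  stopifnot(inherits(field, "vector_field"))
  stop_if_not(length(field$azimuth) >= 4 && length(field$elevation) >= 4,
              "need at least 4 x 4 sample nodes")
  u <- field$lms * cosd(field$lpd)
  v <- field$lms * sind(field$lpd)
  az_out <- seq(min(field$azimuth), max(field$azimuth), by = step)
  el_out <- seq(min(field$elevation), max(field$elevation), by = step)
  ui <- interp2_spline(field$azimuth, field$elevation, u, az_out, el_out)
  vi <- interp2_spline(field$azimuth, field$elevation, v, az_out, el_out)
  vector_field(az_out, el_out, wrap360(atan2d(vi, ui)), sqrt(ui^2 + vi^2))
}

#' Normalise vector fields to the non-polarised reference condition
#'
#' All fields' LMS magnitudes are divided by the maximum LMS of the
#' reference (non-polarised) field, so the reference peaks at 1 and other
#' conditions are expressed relative to it.
#'
#' @param fields Named list of [vector_field()]s.
#' @param reference Name of the reference condition (default `"NP"`).
#' @return List of normalised fields.
#' @export
normalise_field <- function(fields, reference = "NP") {
  stop_if_not(reference %in% names(fields),
              "reference condition '%s' missing", reference)
  mx <- max(fields[[reference]]$lms)
  stop_if_not(mx > 0, "reference maximum must be positive")
  lapply(fields, function(f) {
    f$lms <- f$lms / mx
    f
  })
}
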