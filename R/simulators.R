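#' Polarisation-sensitive photoreceptor model
#'
#' A microvillar photoreceptor with dichroic absorption: photon capture for
#' fully polarised light is maximal at the preferred e-vector `phi_max` and
#' reduced by the polarisation-sensitivity ratio `ps` at the orthogonal
#' angle. Spatially the cell has a Gaussian receptive field; the
#' capture-to-voltage transfer is Naka-Rushton saturation with
#' half-saturation `half_capture` and maximal depolarisation `v_max`.
#'
#' Defaults describe a blue-class butterfly photoreceptor: preferred
#' e-vector along the dorsal-ventral axis (`phi_max = 90` deg), PS ratio 2,
#' acceptance sd 1.5 deg. `half_capture` is large relative to unit capture
#' so responses stay near-linear and measured tuning ratios track the true
#' PS.
#'
#' @param phi_max Preferred e-vector angle (deg; 90 blue-class, 0
#'   green-class).
#' @param ps Polarisation-sensitivity ratio (>= 1).
#' @param rf_centre Receptive-field centre `(azimuth, elevation)` (deg).
#' @param rf_sd Receptive-field Gaussian sd (deg).
#' @param v_max Maximal depolarisation (mV).
#' @param half_capture Half-saturation capture (capture units; intensity 1
#'   fully polarised at `phi_max` gives capture 1).
#' @param noise_sd Additive Gaussian voltage noise sd (mV).
#' @return An object of class `photoreceptor_model`.
#' @export
photoreceptor_model <- function(phi_max = 90, ps = 2, rf_centre = c(0, 0),
                                rf_sd = 1.5, v_max = 40, half_capture = 19,
                                noise_sd = 0.1) {
  stop_if_not(ps >= 1, "ps must be >= 1")
  stop_if_not(rf_sd > 0 && noise_sd >= 0, "rf_sd > 0 and noise_sd >= 0 required")
  structure(list(phi_max = phi_max, ps = ps, rf_centre = rf_centre,
                 rf_sd = rf_sd, v_max = v_max, half_capture = half_capture,
                 noise_sd = noise_sd),
            class = "photoreceptor_model")
}

#' Rhabdom photon capture for partially polarised light
#'
#' For fully polarised light the capture follows the dichroic absorption
#' profile `cos^2(aop - phi_max) + sin^2(aop - phi_max)/ps`; non-polarised
#' light is the average over all e-vectors, `(1 + 1/ps)/2`, which lies
#' strictly between the polarised extremes for `ps > 1`. Partial
#' polarisation mixes the two by the DoLP:
#' `C = I * [(1 - d)(1 + 1/ps)/2 + d (cos^2(a - phi) + sin^2(a - phi)/ps)]`.
#'
#' @param intensity Light intensity (arbitrary linear units).
#' @param dolp Degree of linear polarisation in \[0, 1\].
#' @param aop Angle of polarisation (deg; ignored when `dolp = 0`).
#' @param model A [photoreceptor_model()].
#' @return Photon capture (same units as intensity).
#' @export
photon_capture <- function(intensity, dolp, aop, model) {
  stopifnot(inherits(model, "photoreceptor_model"))
  stop_if_not(all(dolp >= 0 & dolp <= 1), "dolp must lie in [0, 1]")
  da <- aop - model$phi_max
  pol <- cosd(da)^2 + sind(da)^2 / model$ps
  unpol <- (1 + 1 / model$ps) / 2
  intensity * ((1 - dolp) * unpol + dolp * pol)
}

naka_rushton <- function(C, model) model$v_max * C / (C + model$half_capture)

#' Simulate an intracellular photoreceptor trace for a grid protocol
#'
#' Generates the membrane-voltage trace of a model photoreceptor watching
#' the receptive-field mapping protocol: a full-field background with one
#' small square presented per schedule entry. The photon capture seen by
#' the cell during a presentation at angular distance r from the
#' receptive-field centre is the background capture plus the object-minus-
#' background capture weighted by the Gaussian envelope
#' `G = exp(-r^2 / (2 rf_sd^2))`; the voltage is the Naka-Rushton transform
#' of that capture plus Gaussian noise. The trace starts one gap before the
#' first onset so every presentation has a baseline window, and the
#' resting (background-driven) level is its reference.
#'
#' @param schedule A [make_grid_schedule()].
#' @param object,background Lists with `intensity`, `dolp` and optionally
#'   `aop` (deg, default 0) describing the stimulus condition.
#' @param model A [photoreceptor_model()].
#' @param sample_rate Sampling rate (Hz). 30 kHz matches the recordings
#'   this emulates; tests use lower rates for speed.
#' @param seed Optional RNG seed (restores RNG state on exit).
#' @return An [intracellular_trace()] starting at `t0 = -gap_duration`.
#' @export
simulate_photoreceptor_trace <- function(schedule, object, background,
                                         model = photoreceptor_model(),
                                         sample_rate = 30000, seed = NULL) {
  stopifnot(inherits(schedule, "grid_schedule"),
            inherits(model, "photoreceptor_model"))
  gap <- attr(schedule, "gap_duration")
  coords <- grid_coordinates(schedule)
  cap <- function(s) photon_capture(s$intensity, s$dolp,
                                    if (is.null(s$aop)) 0 else s$aop, model)
  c_bg <- cap(background)
  c_obj <- cap(object)
  t0 <- -gap
  t_end <- max(schedule$offset) + gap
  n <- ceiling((t_end - t0) * sample_rate)
  v <- rep(naka_rushton(c_bg, model), n)
  times <- t0 + (seq_len(n) - 1) / sample_rate
  for (i in seq_len(nrow(schedule))) {
    az <- coords$azimuth[schedule$col[i]]
    el <- coords$elevation[schedule$row[i]]
    r2 <- (az - model$rf_centre[1])^2 + (el - model$rf_centre[2])^2
    G <- exp(-r2 / (2 * model$rf_sd^2))
    w <- sample_window(schedule$onset[i], schedule$offset[i], t0, sample_rate)
    v[max(1, w[1]):min(n, w[2])] <- naka_rushton(c_bg + (c_obj - c_bg) * G,
                                                 model)
  }
  if (model$noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(n, 0, model$noise_sd))
  }
  intracellular_trace(v, sample_rate, t0)
}

#' Direction-tuned spiking neuron model (H1-like)
#'
#' An inhomogeneous-Poisson spiking neuron with cosine direction tuning,
#' contrast-squared response gain (the correlator signature), a pure
#' response latency, and a Gaussian spatial sensitivity envelope. The model
#' is polarisation-blind unless `pol_sensitivity` is supplied, in which
#' case the gain is additionally scaled by the photon capture of a
#' polarisation-sensitive front end (useful to preview what a positive
#' polarisation-tuning result looks like).
#'
#' @param theta_pref Preferred motion direction (deg).
#' @param baseline_rate Spontaneous rate (spikes/s).
#' @param gain Rate modulation at |contrast| = 1 (spikes/s).
#' @param latency Response latency (s).
#' @param envelope_centre,envelope_sd Gaussian spatial envelope (deg).
#' @param contrast_exponent Fixed at 2 for the correlator model.
#' @param pol_sensitivity Optional [photoreceptor_model()] front end; NULL
#'   (default) = polarisation-blind.
#' @return An object of class `h1_model`.
#' @export
h1_model <- function(theta_pref = 0, baseline_rate = 20, gain = 80,
                     latency = 0.020, envelope_centre = c(-45, 0),
                     envelope_sd = 40, contrast_exponent = 2,
                     pol_sensitivity = NULL) {
  stop_if_not(baseline_rate >= 0 && gain >= 0, "rates must be non-negative")
  stop_if_not(contrast_exponent == 2,
              "contrast_exponent is fixed at 2 (correlator model)")
  structure(list(theta_pref = theta_pref, baseline_rate = baseline_rate,
                 gain = gain, latency = latency,
                 envelope_centre = envelope_centre, envelope_sd = envelope_sd,
                 contrast_exponent = contrast_exponent,
                 pol_sensitivity = pol_sensitivity),
            class = "h1_model")
}

h1_rate_function <- function(traj, location, contrast, dolp, aop, model) {
  d2 <- sum((location - model$envelope_centre)^2)
  env <- exp(-d2 / (2 * model$envelope_sd^2))
  g <- model$gain * abs(contrast)^model$contrast_exponent
  if (!is.null(model$pol_sensitivity)) {
    g <- g * photon_capture(1, dolp, aop, model$pol_sensitivity)
  }
  function(t) {
    th <- trajectory_angles(traj, t - model$latency)$motion_direction
    pmax(0, model$baseline_rate + g * cosd(th - model$theta_pref)) * env
  }
}

#' Simulate an H1-like spike train for a circular-dot stimulus
#'
#' Draws spikes from the model's inhomogeneous Poisson rate by thinning: a
#' homogeneous Poisson process at the rate ceiling is generated over the
#' trajectory span and each candidate is retained with probability
#' `rate(t) / rate_max`.
#'
#' @param traj A [make_dot_trajectory()].
#' @param location Dot-path centre `(azimuth, elevation)` (deg).
#' @param contrast Signed intensity contrast in \[-1, 1\].
#' @param dolp,aop Polarisation of the dot (used only by a
#'   polarisation-sensitive front end).
#' @param model An [h1_model()].
#' @param seed Optional RNG seed.
#' @return A [spike_train()] matching the trajectory's rotation direction.
#' @export
simulate_h1_spikes <- function(traj, location = c(-45, 0), contrast = 1,
                               dolp = 0, aop = 0, model = h1_model(),
                               seed = NULL) {
  stopifnot(inherits(traj, "dot_trajectory"), inherits(model, "h1_model"))
  rate <- h1_rate_function(traj, location, contrast, dolp, aop, model)
  d2 <- sum((location - model$envelope_centre)^2)
  env <- exp(-d2 / (2 * model$envelope_sd^2))
  g <- model$gain * abs(contrast)^model$contrast_exponent
  if (!is.null(model$pol_sensitivity)) {
    g <- g * photon_capture(1, dolp, aop, model$pol_sensitivity)
  }
  rate_max <- (model$baseline_rate + g) * env
  times <- with_seed(seed, {
    if (rate_max <= 0) numeric(0) else {
      n_cand <- stats::rpois(1, rate_max * traj$duration)
      # unique(): the RNG can produce exact ties at ~1e5 draws, and
      # simultaneous spikes are unphysical
      cand <- unique(sort(stats::runif(n_cand, 0, traj$duration)))
      cand[stats::runif(length(cand)) < rate(cand) / rate_max]
    }
  })
  spike_train(times, direction = traj$direction,
              condition = sprintf("contrast=%g dolp=%g aop=%g",
                                  contrast, dolp, aop),
              location = location)
}

#' Simulated dual-projector device with intrinsic polarisation
#'
#' Each LED's luminance varies sinusoidally with polariser angle (intrinsic
#' DLP polarisation) and linearly with drive current.
#'
#' @param leds Named list; each element a list with `offset`, `amplitude`,
#'   `phase` (deg) and optionally `gain` (luminance per unit current,
#'   default 1).
#' @return An object of class `simulated_device`.
#' @export
simulated_device <- function(leds = list(
    blue_pol = list(offset = 6.0, amplitude = 1.2, phase = 20),
    blue_np = list(offset = 5.5, amplitude = 0.0, phase = 0),
    green_pol = list(offset = 5.0, amplitude = 1.0, phase = 110),
    green_np = list(offset = 4.2, amplitude = 0.0, phase = 0))) {
  for (nm in names(leds)) {
    l <- leds[[nm]]
    stop_if_not(l$offset >= l$amplitude && l$amplitude >= 0,
                "LED '%s' luminance would go negative", nm)
  }
  structure(list(leds = leds), class = "simulated_device")
}

#' Photodiode reading from the simulated device
#'
#' `L = current * gain * (offset + amplitude * cos(2 (theta - phase)))`;
#' deterministic, monotone in current.
#'
#' @param device A [simulated_device()].
#' @param led LED name.
#' @param current Drive current (>= 0).
#' @param theta Polariser angle (deg).
#' @return Luminance (arbitrary linear units).
#' @export
simulated_photodiode <- function(device, led, current, theta) {
  stopifnot(inherits(device, "simulated_device"))
  stop_if_not(led %in% names(device$leds), "unknown LED '%s'", led)
  stop_if_not(all(current >= 0), "current must be >= 0")
  l <- device$leds[[led]]
  gain <- if (is.null(l$gain)) 1 else l$gain
  current * gain * (l$offset + l$amplitude * cosd(2 * (theta - l$phase)))
}
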