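#' Fit a polariser-angle luminance model to photodiode samples
#'
#' Because of intrinsic projector polarisation, measured LED luminance varies
#' sinusoidally with the polariser angle theta with a 180-deg period:
#' `L(theta) = offset + amplitude * cos(2 * (theta - phase))`. The fit is
#' linear least squares on the basis `(1, cos 2theta, sin 2theta)`; amplitude
#' is non-negative by construction and phase is reported in \[0, 180) deg.
#'
#' @param theta Polariser angles (deg).
#' @param luminance Measured luminances (linear arbitrary units).
#' @return An object of class `led_luminance_model`: `offset`, `amplitude`,
#'   `phase` (deg), `residual_norm`.
#' @export
fit_polariser_sinusoid <- function(theta, luminance) {
  stop_if_not(length(theta) == length(luminance) && length(theta) >= 3,
              "need >= 3 (theta, luminance) samples")
  X <- cbind(1, cosd(2 * theta), sind(2 * theta))
  # qr()'s pivot-based rank misses near-zero columns here; use the SVD
  sv <- svd(X)$d
  stop_if_not(sv[3] > 1e-8 * sv[1],
    "angle sampling is rank-deficient: need >= 3 distinct angles mod 180 deg")
  qrX <- qr(X)
  beta <- qr.coef(qrX, luminance)
  amplitude <- sqrt(beta[2]^2 + beta[3]^2)
  phase <- if (amplitude < 1e-12 * max(1, abs(beta[1]))) 0 else {
    ((rad2deg(atan2(beta[3], beta[2])) / 2) %% 180 + 180) %% 180
  }
  structure(list(offset = unname(beta[1]), amplitude = unname(amplitude),
                 phase = unname(phase),
                 residual_norm = sqrt(sum(qr.resid(qrX, luminance)^2))),
            class = "led_luminance_model")
}

#' Evaluate an LED luminance model
#'
#' `L(theta, current) = current * (offset + amplitude * cos(2 (theta - phase)))`,
#' assuming luminance linear in drive current.
#'
#' @param model A `led_luminance_model`.
#' @param theta Polariser angle(s), deg.
#' @param current Drive current (arbitrary units, default 1).
#' @export
led_luminance <- function(model, theta, current = 1) {
  stopifnot(inherits(model, "led_luminance_model"))
  current * (model$offset + model$amplitude * cosd(2 * (theta - model$phase)))
}

#' Select the calibration target luminance
#'
#' The lowest uncalibrated luminance across all LEDs and polariser angles is
#' designated the target every LED is dimmed/driven to match, so that every
#' LED can reach it without exceeding its drive range. For a sinusoidal
#' model the per-LED minimum over angle is `current * (offset - amplitude)`.
#'
#' @param models List of `led_luminance_model`s (optionally with a `current`
#'   field giving the uncalibrated drive current; default 1).
#' @return The target luminance (minimum over LEDs of the angular minimum).
#' @export
select_calibration_target <- function(models) {
  stop_if_not(length(models) >= 1, "need at least one LED model")
  mins <- vapply(models, function(m) {
    cur <- if (!is.null(m$current)) m$current else 1
    cur * (m$offset - m$amplitude)
  }, numeric(1))
  min(mins)
}

#' Equalise one LED to a target luminance at a fixed polariser angle
#'
#' Adjusts drive current until the measured luminance matches the target,
#' querying `oracle(current, theta)` (a photodiode in hardware, a simulated
#' device in tests). The current-to-luminance map is assumed monotone
#' non-decreasing; the solver brackets the target by doubling and then
#' refines by bisection with a secant step, a damped descent on the
#' monotone map. Convergence is relative luminance error <= `tolerance`.
#'
#' @param oracle Function `(current, theta) -> luminance`.
#' @param target Target luminance (> 0).
#' @param theta Polariser angle (deg).
#' @param tolerance Relative luminance tolerance (default 0.005 = 0.5%).
#' @param max_iter Iteration budget.
#' @param current_init Starting current guess.
#' @param current_max Largest admissible current while bracketing.
#' @return A list `current`, `luminance`, `iterations`, `converged`, and
#'   `trace` (data.frame of visited currents/luminances). Non-convergence
#'   returns `converged = FALSE` with a warning rather than an error, so a
#'   calibration run can report per-angle failures.
#' @export
equalise_led <- function(oracle, target, theta, tolerance = 0.005,
                         max_iter = 100, current_init = 1,
                         current_max = 1e6) {
  stop_if_not(is_number(target) && target > 0, "target must be positive")
  trace <- list()
  note <- function(c, L) trace[[length(trace) + 1]] <<- c(current = c, luminance = L)
  rel_err <- function(L) abs(L - target) / target

  lo <- 0; L_lo <- oracle(0, theta); note(lo, L_lo)
  hi <- max(current_init, .Machine$double.eps)
  L_hi <- oracle(hi, theta); note(hi, L_hi)
  iter <- 2
  while (L_hi < target && hi < current_max && iter < max_iter) {
    lo <- hi; L_lo <- L_hi
    hi <- hi * 2
    L_hi <- oracle(hi, theta); note(hi, L_hi)
    iter <- iter + 1
  }
  done <- function(cur, L, conv) {
    tr <- as.data.frame(do.call(rbind, trace))
    if (!conv) warning(sprintf(
      "equalise_led: no convergence at theta=%g (best rel. error %.3g)",
      theta, rel_err(L)), call. = FALSE)
    list(current = cur, luminance = L, iterations = iter,
         converged = conv, trace = tr)
  }
  if (L_hi < target) return(done(hi, L_hi, FALSE))  # target unreachable
  if (rel_err(L_hi) <= tolerance) return(done(hi, L_hi, TRUE))
  if (rel_err(L_lo) <= tolerance) return(done(lo, L_lo, TRUE))

  while (iter < max_iter) {
    # secant proposal, fall back to bisection when outside the bracket
    mid <- if (L_hi > L_lo) lo + (target - L_lo) * (hi - lo) / (L_hi - L_lo)
           else (lo + hi) / 2
    if (!is.finite(mid) || mid <= lo || mid >= hi) mid <- (lo + hi) / 2
    L_mid <- oracle(mid, theta); note(mid, L_mid)
    iter <- iter + 1
    if (rel_err(L_mid) <= tolerance) return(done(mid, L_mid, TRUE))
    if (L_mid < target) { lo <- mid; L_lo <- L_mid }
    else { hi <- mid; L_hi <- L_mid }
  }
  best <- if (rel_err(L_lo) < rel_err(L_hi)) list(lo, L_lo) else list(hi, L_hi)
  done(best[[1]], best[[2]], FALSE)
}

#' Build a polariser-angle-dependent calibration look-up table
#'
#' Runs [equalise_led()] at every angle of `angle_grid` and tabulates the
#' currents that drive the LED to the target luminance.
#'
#' @inheritParams equalise_led
#' @param angle_grid Polariser angles to tabulate (deg).
#' @param led_id Label stored in the table.
#' @return An object of class `calibration_lut`: data.frame with columns
#'   `led_id`, `angle_deg`, `current`, `luminance`, `converged`; the target
#'   and tolerance are attributes.
#' @export
build_lut <- function(oracle, target, angle_grid = seq(0, 165, by = 15),
                      tolerance = 0.005, max_iter = 100, led_id = "LED") {
  rows <- lapply(angle_grid, function(th) {
    r <- equalise_led(oracle, target, th, tolerance, max_iter)
    data.frame(led_id = led_id, angle_deg = th, current = r$current,
               luminance = r$luminance, converged = r$converged)
  })
  structure(do.call(rbind, rows),
            class = c("calibration_lut", "data.frame"),
            target = target, tolerance = tolerance)
}

#' Check the calibration-table luminance invariant
#'
#' @param lut A [build_lut()] result.
#' @return Maximum relative luminance deviation from the target across the
#'   tabulated angles.
#' @export
lut_max_deviation <- function(lut) {
  stopifnot(inherits(lut, "calibration_lut"))
  target <- attr(lut, "target")
  max(abs(lut$luminance - target) / target)
}
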