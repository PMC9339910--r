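# Shared fixtures. Everything is generated in code; seeds are fixed so the
# stochastic recovery tests are reproducible.

# A display small enough to rasterise quickly but with the same 4-bit,
# 24-bit, 60 Hz timing semantics as the real device.
tiny_spec <- function(px = 48, dpp = 0.5) {
  display_spec(width = px, height = px, degrees_per_pixel = dpp)
}

# Smallest angular difference (deg) between two directions.
ang_err <- function(a, b) abs(wrap180(a - b))

# Independent circular-mean oracle: explicit unit-vector summation on
# complex numbers (kept deliberately separate from circular_mean()).
oracle_circ_mean <- function(angles_deg) {
  z <- sum(exp(1i * angles_deg * pi / 180))
  list(mean = (Arg(z) * 180 / pi) %% 360, R = Mod(z) / length(angles_deg))
}

# One full fast-protocol local-motion estimate from a simulated H1 cell.
sim_estimate <- function(model, contrast = 1, dolp = 0, aop = 0,
                         location = c(0, 0), seed = 1,
                         sample_rate = 360) {
  tcw <- make_dot_trajectory("CW", sample_rate)
  tccw <- make_dot_trajectory("CCW", sample_rate)
  scw <- simulate_h1_spikes(tcw, location, contrast, dolp, aop, model,
                            seed = seed)
  sccw <- simulate_h1_spikes(tccw, location, contrast, dolp, aop, model,
                             seed = seed + 5000L)
  estimate_local_motion(scw, sccw, tcw, tccw)
}

# Receptive-field maps of a simulated photoreceptor for a set of stimulus
# conditions, on a reduced grid / sampling rate for test speed.
sim_pr_maps <- function(model, conditions, schedule = make_grid_schedule(c(10, 10)),
                        sample_rate = 1000, seed = 1) {
  background <- list(intensity = 0, dolp = 0)
  maps <- lapply(seq_along(conditions), function(i) {
    tr <- simulate_photoreceptor_trace(schedule, conditions[[i]], background,
                                       model, sample_rate,
                                       seed = seed * 100L + i)
    build_rf_map(tr, schedule)
  })
  names(maps) <- names(conditions)
  maps
}

# Standard condition set: fully polarised objects at four AoPs plus the
# non-polarised reference, all at full intensity on a dark background.
pr_conditions <- function() {
  cond <- lapply(c(0, 45, 90, 135), function(a)
    list(intensity = 1, dolp = 1, aop = a))
  names(cond) <- c("0", "45", "90", "135")
  c(cond, list(NP = list(intensity = 1, dolp = 0)))
}
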