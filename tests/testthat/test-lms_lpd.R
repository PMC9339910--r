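test_that("spike-triggered motion directions follow the tangent geometry", {
  traj <- make_dot_trajectory("CCW", 360)
  empty <- spike_motion_directions(spike_train(numeric(0)), traj)
  expect_equal(length(empty), 0L)
  # spike at t = 0 (psi = 0): CCW tangent is 90 deg, CW is 270 deg
  expect_equal(as.vector(spike_motion_directions(spike_train(0), traj)), 90)
  expect_equal(as.vector(spike_motion_directions(
    spike_train(0), make_dot_trajectory("CW", 360))), 270)
  # out-of-span spikes are dropped and counted
  th <- spike_motion_directions(spike_train(c(1, 99)), traj)
  expect_equal(length(th), 1L)
  expect_equal(attr(th, "n_dropped"), 1L)
  # uniform raster -> uniform direction histogram (chi-square)
  m <- h1_model(envelope_centre = c(0, 0))
  tr <- simulate_h1_spikes(make_dot_trajectory("CCW", 360, n_cycles = 100),
                           c(0, 0), contrast = 0, model = m, seed = 31)
  dirs <- spike_motion_directions(tr, make_dot_trajectory("CCW", 360,
                                                          n_cycles = 100))
  counts <- table(cut(dirs, seq(0, 360, by = 45)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("circular_mean matches vector summation and flags degeneracy", {
  expect_equal(circular_mean(c(10, 20, 30))$mean, 20, tolerance = 1e-12)
  expect_equal(circular_mean(42)$R, 1)
  expect_equal(circular_mean(42)$mean, 42)
  anti <- circular_mean(c(0, 180))
  expect_true(is.na(anti$mean))
  expect_lt(anti$R, 1e-12)
  expect_error(circular_mean(numeric(0)), "non-empty")
  set.seed(12)
  for (i in 1:50) {
    a <- runif(sample(1:40, 1), 0, 360)
    got <- circular_mean(a)
    want <- oracle_circ_mean(a)
    expect_equal(got$R, want$R, tolerance = 1e-12)
    if (want$R > 1e-6) expect_lt(ang_err(got$mean, want$mean), 1e-10)
  }
})

test_that("latency-corrected LPD is the resultant of the two estimates", {
  expect_equal(latency_corrected_lpd(30, 30), 30)
  for (d in c(10, 45, 80)) {
    expect_equal(latency_corrected_lpd(135 + d, 135 - d), 135,
                 tolerance = 1e-9)
  }
  expect_warning(out <- latency_corrected_lpd(10, 190), "antipodal")
  expect_true(is.na(out))
})

test_that("sector rates use dwell-time normalisation", {
  traj <- make_dot_trajectory("CW", 360)
  expect_equal(sector_rate(spike_train(numeric(0), direction = "CW"),
                           traj, 90), 0)
  # full-circle sector recovers the overall mean rate
  tr <- spike_train(seq(0.01, 4.99, length.out = 50), direction = "CW")
  expect_equal(sector_rate(tr, traj, 0, halfwidth = 180), 10)
  # homogeneous Poisson: any 90-deg sector estimates the true rate
  m <- h1_model(baseline_rate = 10, envelope_centre = c(0, 0))
  tlong <- make_dot_trajectory("CW", 360, n_cycles = 200)
  sim <- simulate_h1_spikes(tlong, c(0, 0), contrast = 0, model = m, seed = 8)
  for (ctr in c(0, 77, 200)) {
    r <- sector_rate(sim, tlong, ctr)
    expect_lt(abs(r - 10) / 10, 0.15)  # ~250 spikes in sector
  }
  expect_error(sector_rate(tr, traj, 0, halfwidth = 0), "halfwidth")
})

test_that("lms is the mean preferred-minus-antipreferred rate difference", {
  expect_equal(lms(20, 20, 0, 0), 20)
  expect_equal(lms(7, 7, 7, 7), 0)
  expect_equal(lms(10, 20, 0, 0), 15)
  expect_error(lms(-1, 0, 0, 0), "non-negative")
})

test_that("estimate_local_motion recovers simulated tuning", {
  model <- h1_model(theta_pref = 135, latency = 0.02,
                    envelope_centre = c(0, 0))
  ests <- lapply(1:10, function(s) sim_estimate(model, seed = s * 11))
  lpds <- vapply(ests, `[[`, numeric(1), "lpd")
  expect_lt(stats::median(ang_err(lpds, 135)), 5)
  # generative LMS: a - b with sector-mean cosine factor sin(45)/(pi/4)
  cf <- sin(pi / 4) / (pi / 4)
  gen <- (20 + 80 * cf) - mean(pmax(0, 20 - 80 * cosd(seq(-44.9, 44.9, 0.1))))
  lmss <- vapply(ests, `[[`, numeric(1), "lms")
  expect_lt(abs(mean(lmss) - gen) / gen, 0.15)
  # untuned neuron: LMS mean within 2 sd of zero (selection bias permitted)
  lms0 <- vapply(1:20, function(s)
    sim_estimate(model, contrast = 0, seed = s * 13)$lms, numeric(1))
  expect_lt(abs(mean(lms0)), 2 * stats::sd(lms0))
})

test_that("doubling the gain doubles LMS in the rectification-free regime", {
  m1 <- h1_model(theta_pref = 0, baseline_rate = 100, gain = 20,
                 latency = 0, envelope_centre = c(0, 0))
  m2 <- h1_model(theta_pref = 0, baseline_rate = 100, gain = 40,
                 latency = 0, envelope_centre = c(0, 0))
  l1 <- mean(vapply(1:20, function(s) sim_estimate(m1, seed = s)$lms,
                    numeric(1)))
  l2 <- mean(vapply(1:20, function(s) sim_estimate(m2, seed = s + 999)$lms,
                    numeric(1)))
  expect_lt(abs(l2 / l1 - 2), 0.3)
})

test_that("tuning aggregation averages within animals before across", {
  df <- data.frame(contrast = c(1, 1, 1), animal = c("A", "A", "B"),
                   lms = c(10, 20, 40))
  out <- contrast_tuning(df)
  expect_equal(out$lms_mean, mean(c(15, 40)))  # not the pooled mean 23.3
  expect_equal(out$n_animals, 2L)
  single <- contrast_tuning(data.frame(contrast = 0.5, animal = "A", lms = 3))
  expect_equal(nrow(single), 1L)
  expect_true(is.na(single$lms_sd))
  aop <- aop_tuning(data.frame(aop = c(0, 0, 45, 45),
                               animal = rep(c("A", "B"), 2),
                               lms = c(1, 3, 5, 7)))
  expect_equal(aop$lms_mean, c(2, 6))
  expect_equal(aop$aop, c(0, 45))
})

test_that("vector-field interpolation preserves nodes and linear fields", {
  az <- seq(-120, 30, by = 30)   # 6 nodes
  el <- seq(-75, 75, by = 30)    # 6 nodes
  uniform <- vector_field(az, el, matrix(40, 6, 6), matrix(2, 6, 6))
  ui <- interpolate_vector_field(uniform, step = 15)
  expect_true(all(abs(ui$lpd - 40) < 1e-9))
  expect_true(all(abs(ui$lms - 2) < 1e-9))
  # linearly varying Cartesian components are reproduced exactly
  u <- outer(el, az, function(e, a) 0.01 * a + 0.02 * e + 1)
  v <- outer(el, az, function(e, a) -0.03 * a + 0.5)
  f <- vector_field(az, el, wrap360(atan2d(v, u)), sqrt(u^2 + v^2))
  fi <- interpolate_vector_field(f, step = 15)
  ue <- outer(fi$elevation, fi$azimuth, function(e, a) 0.01 * a + 0.02 * e + 1)
  ve <- outer(fi$elevation, fi$azimuth, function(e, a) -0.03 * a + 0.5)
  expect_equal(fi$lms * cosd(fi$lpd), ue, tolerance = 1e-9)
  expect_equal(fi$lms * sind(fi$lpd), ve, tolerance = 1e-9)
  # sampled nodes sit on the refined grid and keep their values
  i_az <- match(az, fi$azimuth); i_el <- match(el, fi$elevation)
  expect_equal(fi$lms[i_el, i_az], f$lms, tolerance = 1e-9)
  expect_error(interpolate_vector_field(
    vector_field(az[1:3], el, matrix(0, 6, 3), matrix(1, 6, 3))), "4 x 4")
})

test_that("field normalisation is anchored to the non-polarised maximum", {
  az <- seq(-120, 30, by = 30); el <- seq(-75, 75, by = 30)
  np <- vector_field(az, el, matrix(0, 6, 6), matrix(runif(36, 0, 40), 6, 6))
  pol <- vector_field(az, el, matrix(0, 6, 6), np$lms / 2)
  out <- normalise_field(list(NP = np, pol = pol))
  expect_equal(max(out$NP$lms), 1)
  expect_equal(out$pol$lms, out$NP$lms / 2, tolerance = 1e-12)
  expect_error(normalise_field(list(pol = pol)), "missing")
  zero <- vector_field(az, el, matrix(0, 6, 6), matrix(0, 6, 6))
  expect_error(normalise_field(list(NP = zero)), "positive")
})
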