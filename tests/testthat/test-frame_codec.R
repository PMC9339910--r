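test_that("encode_pixel hits the documented endpoints and rounding rule", {
  spec <- display_spec()
  expect_equal(encode_pixel(pol_pixel_command(1, 1), spec),
               list(g_pol = 15L, g_nonpol = 0L))
  expect_equal(encode_pixel(pol_pixel_command(1, 0), spec),
               list(g_pol = 0L, g_nonpol = 15L))
  expect_equal(encode_pixel(pol_pixel_command(0, 0.7), spec),
               list(g_pol = 0L, g_nonpol = 0L))
  # round-half-away-from-zero: dolp 0.5 of total 15 -> 8 polarised, 7 not
  expect_equal(encode_pixel(pol_pixel_command(1, 0.5), spec),
               list(g_pol = 8L, g_nonpol = 7L))
  expect_error(pol_pixel_command(1.2, 0), "intensity")
  expect_error(pol_pixel_command(0.5, -0.1), "dolp")
})

test_that("greyscale conservation and achieved-DoLP monotonicity hold", {
  spec <- display_spec()
  dolp <- seq(0, 1, length.out = 4097)
  enc <- encode_pixel(pol_pixel_command(rep(1, length(dolp)), dolp), spec)
  expect_true(all(enc$g_pol + enc$g_nonpol == spec$max_grey))
  achieved <- enc$g_pol / (enc$g_pol + enc$g_nonpol)
  expect_true(all(diff(achieved) >= 0))
  # at partial intensity the sum equals the rounded total and never exceeds it
  enc2 <- encode_pixel(pol_pixel_command(rep(0.6, length(dolp)), dolp), spec)
  expect_true(all(enc2$g_pol + enc2$g_nonpol == 9L))
})

test_that("encode_frame equals the pixelwise map and handles edge shapes", {
  spec <- display_spec()
  set.seed(42)
  intens <- matrix(runif(35), 5, 7)
  dolp <- matrix(runif(35), 5, 7)
  fp <- encode_frame(intens, dolp, spec)
  for (i in seq_len(5)) for (j in seq_len(7)) {
    e <- encode_pixel(pol_pixel_command(intens[i, j], dolp[i, j]), spec)
    expect_identical(fp$g_pol[i, j], e$g_pol)
    expect_identical(fp$g_nonpol[i, j], e$g_nonpol)
  }
  empty <- encode_frame(matrix(0, 0, 0), matrix(0, 0, 0), spec)
  expect_equal(dim(empty$g_pol), c(0L, 0L))
  expect_error(encode_frame(matrix(0, 2, 2), matrix(0, 3, 2), spec),
               "dimensions")
})

test_that("pack/unpack round-trips and encodes the documented bit dialect", {
  spec <- display_spec()
  zero <- lapply(1:6, function(i) matrix(0L, 2, 2))
  packed <- pack_video_frames(zero, spec)
  expect_equal(length(packed), 1L)
  expect_true(all(packed[[1]] == 0L))
  full <- lapply(1:6, function(i) matrix(15L, 2, 2))
  expect_true(all(pack_video_frames(full, spec)[[1]] == 255L))
  # subframe 1 is the low nibble of the blue byte (B,R,G order, LSB first)
  one <- c(list(matrix(3L, 1, 1)), lapply(1:5, function(i) matrix(0L, 1, 1)))
  p <- pack_video_frames(one, spec)[[1]]
  expect_equal(unname(p[1, 1, "B"]), 3L)
  expect_equal(unname(p[1, 1, "R"]), 0L)
  expect_equal(unname(p[1, 1, "G"]), 0L)
  # random 1x1 stacks round-trip exactly (>= 1e4 of the 16^6 combinations)
  set.seed(7)
  subs <- lapply(seq_len(6 * 10000), function(i)
    matrix(sample(0:15, 1), 1, 1))
  expect_identical(unpack_video_frames(pack_video_frames(subs, spec), spec),
                   subs)
  expect_error(pack_video_frames(lapply(1:6, function(i) matrix(16L, 1, 1)),
                                 spec), "0..15")
  expect_error(pack_video_frames(zero[1:5], spec), "multiple")
})

test_that("pattern_rate follows video_rate * bits / depth", {
  expect_equal(pattern_rate(display_spec()), 360)
  expect_equal(pattern_rate(display_spec(bit_depth = 24)), 60)
  expect_equal(pattern_rate(display_spec(video_rate = 120)), 720)
  expect_error(display_spec(bit_depth = 5), "divisible")
})

test_that("stimulus_contrast spans the printed -1/0/+1 endpoints", {
  expect_equal(stimulus_contrast(0, 1), -1)
  expect_equal(stimulus_contrast(1, 1), 0)
  expect_equal(stimulus_contrast(1, 0), 1)
  expect_error(stimulus_contrast(2, 0), "0, 1")
})

test_that("dot trajectories obey the tangent geometry and duration", {
  for (dirn in c("CW", "CCW")) {
    traj <- make_dot_trajectory(dirn, sample_rate = 360)
    expect_equal(traj$duration, 5)            # 10 cycles / 2 Hz
    expect_equal(length(traj$times), 1800L)   # 5 s at 360 Hz
    s <- if (dirn == "CCW") 90 else -90
    expect_equal(max(abs(wrap180(traj$motion_direction -
                                   (traj$position_angle + s)))), 0)
  }
  expect_equal(trajectory_angles(make_dot_trajectory("CCW", 100), 0)$motion_direction, 90)
  expect_equal(trajectory_angles(make_dot_trajectory("CW", 100), 0)$motion_direction, 270)
  expect_error(make_dot_trajectory("CW", 0), "sample_rate")
})

test_that("grid schedules scan row-major with the documented timing", {
  sch <- make_grid_schedule()
  expect_equal(nrow(sch), 400L)
  expect_equal(sch$onset, (seq_len(400) - 1) * 0.150)
  expect_equal(sch$offset - sch$onset, rep(0.100, 400))
  expect_equal(max(sch$offset) + 0.050, 60)
  expect_equal(sch$row[1:21], c(rep(1L, 20), 2L))  # row-major from top-left
  expect_true(all(sch$onset[-1] >= sch$offset[-400]))  # non-overlapping
  one <- make_grid_schedule(c(1, 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$onset, 0)
})

test_that("render_frames places the dot per the trajectory and toggles sync", {
  spec <- tiny_spec()
  traj <- make_dot_trajectory("CCW", sample_rate = 12, dot_diameter = 4,
                              path_diameter = 8, frequency = 2, n_cycles = 1)
  obj <- pol_pixel_command(1, 1)
  bg <- pol_pixel_command(0.5, 0)
  out <- render_frames(traj, obj, bg, spec, sync_size = 4)
  expect_equal(out$sync, rep(c(0L, 1L), 3))
  # dot centre (mean of object pixels) tracks psi(t) within one pixel
  for (i in c(1, 3, 5)) {
    fp <- out$frames[[i]]
    mask <- fp$g_pol == 15
    mask[(spec$height - 3):spec$height, 1:4] <- FALSE  # drop sync patch
    az_exp <- 4 * cosd(traj$position_angle[i])
    el_exp <- 4 * sind(traj$position_angle[i])
    p <- angles_to_pixels(az_exp, el_exp, spec)
    expect_lt(abs(mean(row(mask)[mask]) - p$row), 1)
    expect_lt(abs(mean(col(mask)[mask]) - p$col), 1)
  }
  # object == background (and no sync patch) renders uniformly
  u <- render_frames(traj, bg, bg, spec, sync_size = 0)
  expect_equal(length(unique(as.vector(u$frames[[1]]$g_pol))), 1L)
  # geometry that does not fit is rejected
  big <- make_dot_trajectory("CW", 12, dot_diameter = 10, path_diameter = 40)
  expect_error(render_frames(big, obj, bg, spec), "fit")
})

test_that("rendered sequence emits pattern_rate subframes per second", {
  spec <- tiny_spec()
  rate <- pattern_rate(spec)
  traj <- make_dot_trajectory("CW", sample_rate = rate, dot_diameter = 2,
                              path_diameter = 6, frequency = 2, n_cycles = 1)
  out <- render_frames(traj, pol_pixel_command(1, 1),
                       pol_pixel_command(0, 0), spec)
  expect_equal(length(out$frames) / traj$duration, rate)
})

test_that("grid rendering lights the scheduled cell only", {
  spec <- tiny_spec()
  sch <- make_grid_schedule(c(3, 3), square_size = 2)
  out <- render_frames(sch, pol_pixel_command(1, 0), pol_pixel_command(0, 0),
                       spec, sync_size = 0)
  expect_equal(length(out$frames), 9L)
  coords <- grid_coordinates(sch)
  fp <- out$frames[[2]]   # row 1, col 2
  mask <- fp$g_nonpol > 0
  p <- angles_to_pixels(coords$azimuth[2], coords$elevation[1], spec)
  expect_lt(abs(mean(row(mask)[mask]) - p$row), 1)
  expect_lt(abs(mean(col(mask)[mask]) - p$col), 1)
})
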