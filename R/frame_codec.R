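#' Display specification for a dual-DLP stimulation device
#'
#' Describes how the graphics pipeline delivers high-rate greyscale subframes:
#' 24-bit RGB video frames at `video_rate` Hz are parsed by each projector in
#' `channel_order` byte order as consecutive `bit_depth`-bit greyscale
#' subframes per pixel, multiplying the effective pattern frame rate by
#' `bits_per_video_frame / bit_depth`.
#'
#' @param video_rate Video frame rate delivered by the graphics card (Hz).
#' @param bits_per_video_frame Bits per pixel of a video frame (24 for RGB).
#' @param channel_order Byte order in which the projector reads the 24-bit
#'   word; `"BRG"` for the LightCrafter-style firmware modelled here.
#' @param bit_depth Greyscale bit depth of each subframe (4 gives levels 0-15).
#' @param width,height Display resolution in pixels.
#' @param degrees_per_pixel Angular subtense of one pixel at the animal's eye.
#' @return An object of class `display_spec` with derived fields
#'   `subframes_per_frame` and `max_grey`.
#' @examples
#' spec <- display_spec()
#' spec$max_grey            # 15
#' pattern_rate(spec)       # 360
#' @export
display_spec <- function(video_rate = 60, bits_per_video_frame = 24,
                         channel_order = "BRG", bit_depth = 4,
                         width = 608, height = 684,
                         degrees_per_pixel = 0.1) {
  stop_if_not(is_number(video_rate) && video_rate > 0,
              "video_rate must be a positive number")
  stop_if_not(is_number(bits_per_video_frame) && bits_per_video_frame > 0,
              "bits_per_video_frame must be a positive integer")
  stop_if_not(is_number(bit_depth) && bit_depth >= 1,
              "bit_depth must be a positive integer")
  stop_if_not(bits_per_video_frame %% bit_depth == 0,
              "bits_per_video_frame (%d) must be divisible by bit_depth (%d)",
              bits_per_video_frame, bit_depth)
  structure(list(
    video_rate = video_rate,
    bits_per_video_frame = as.integer(bits_per_video_frame),
    channel_order = channel_order,
    bit_depth = as.integer(bit_depth),
    width = as.integer(width),
    height = as.integer(height),
    degrees_per_pixel = degrees_per_pixel,
    subframes_per_frame = as.integer(bits_per_video_frame / bit_depth),
    max_grey = as.integer(2^bit_depth - 1)
  ), class = "display_spec")
}

#' Pattern frame rate of a display specification
#'
#' The rate at which greyscale subframes reach the eye:
#' `video_rate * bits_per_video_frame / bit_depth`. For the default
#' 60 Hz / 24-bit / 4-bit configuration this is 360 Hz, above the flicker
#' fusion frequency of most insect photoreceptors.
#'
#' @param spec A [display_spec()].
#' @return Pattern frame rate in Hz.
#' @export
pattern_rate <- function(spec) {
  stopifnot(inherits(spec, "display_spec"))
  spec$video_rate * spec$bits_per_video_frame / spec$bit_depth
}

#' Pixel command: requested intensity and degree of linear polarisation
#'
#' @param intensity Fraction of maximal luminance, in \[0, 1\].
#' @param dolp Requested degree of linear polarisation, in \[0, 1\].
#' @return An object of class `pol_pixel_command`.
#' @export
pol_pixel_command <- function(intensity, dolp) {
  stop_if_not(all(is.finite(intensity)) && all(intensity >= 0) &&
                all(intensity <= 1), "intensity must lie in [0, 1]")
  stop_if_not(all(is.finite(dolp)) && all(dolp >= 0) && all(dolp <= 1),
              "dolp must lie in [0, 1]")
  structure(list(intensity = intensity, dolp = dolp),
            class = "pol_pixel_command")
}

#' Encode an intensity/DoLP command into dual-channel greyscale values
#'
#' The total luminance is shared between the polarised projector (DLP1) and
#' the non-polarised projector (DLP2). The summed greyscale value fixes the
#' luminance and the fraction emitted by the polarised channel fixes the
#' DoLP: at full intensity the two values always sum to `max_grey` (15),
#' with maximal DoLP at (15, 0) and minimal DoLP at (0, 15).
#'
#' Quantisation is round-half-away-from-zero applied first to the total,
#' then to the polarised share; the non-polarised channel takes the
#' remainder, so the sum constraint holds exactly.
#'
#' @param cmd A [pol_pixel_command()] (vectorised over its fields).
#' @param spec A [display_spec()].
#' @return A list with integer components `g_pol` and `g_nonpol`.
#' @examples
#' encode_pixel(pol_pixel_command(1, 1), display_spec())   # 15, 0
#' encode_pixel(pol_pixel_command(1, 0), display_spec())   # 0, 15
#' @export
encode_pixel <- function(cmd, spec = display_spec()) {
  stopifnot(inherits(cmd, "pol_pixel_command"), inherits(spec, "display_spec"))
  total <- round_half_away(cmd$intensity * spec$max_grey)
  g_pol <- round_half_away(cmd$dolp * total)
  list(g_pol = as.integer(g_pol), g_nonpol = as.integer(total - g_pol))
}

#' Encode per-pixel command images into a frame pair
#'
#' Vectorised [encode_pixel()]: `intensity` and `dolp` are matrices of equal
#' dimensions giving the command at every pixel.
#'
#' @param intensity,dolp Numeric matrices in \[0, 1\] with identical dims.
#' @param spec A [display_spec()].
#' @return An object of class `frame_pair`: integer matrices `g_pol` (the
#'   polarised channel, DLP1) and `g_nonpol` (DLP2).
#' @export
encode_frame <- function(intensity, dolp, spec = display_spec()) {
  stop_if_not(is.matrix(intensity) && is.matrix(dolp),
              "intensity and dolp must be matrices")
  stop_if_not(all(dim(intensity) == dim(dolp)),
              "intensity and dolp dimensions differ")
  cmd <- pol_pixel_command(as.numeric(intensity), as.numeric(dolp))
  enc <- encode_pixel(cmd, spec)
  fp <- list(g_pol = matrix(enc$g_pol, nrow(intensity), ncol(intensity)),
             g_nonpol = matrix(enc$g_nonpol, nrow(intensity), ncol(intensity)))
  class(fp) <- "frame_pair"
  fp
}

#' Pack greyscale subframes into 24-bit video frames
#'
#' Consecutive groups of `subframes_per_frame` subframes are packed into one
#' 24-bit RGB video frame read by the projector in B,R,G byte order:
#' subframe i (0-based within the group) occupies bits `[4i, 4i+4)` of the
#' word, least-significant bit first, so subframes 1-2 fill the blue byte,
#' 3-4 the red byte and 5-6 the green byte. `unpack_video_frames()` inverts
#' the packing exactly.
#'
#' @param subframes List of integer matrices with values in `0..max_grey`,
#'   length a multiple of `spec$subframes_per_frame`.
#' @param spec A [display_spec()] with `bit_depth = 4` semantics.
#' @return List of packed frames; each is an `height x width x 3` integer
#'   array with channels named R, G, B (byte values 0-255).
#' @export
pack_video_frames <- function(subframes, spec = display_spec()) {
  stopifnot(inherits(spec, "display_spec"), is.list(subframes))
  spf <- spec$subframes_per_frame
  stop_if_not(length(subframes) %% spf == 0,
              "number of subframes (%d) is not a multiple of %d",
              length(subframes), spf)
  per_byte <- 8L %/% spec$bit_depth
  stop_if_not(per_byte >= 1 && 8 %% spec$bit_depth == 0,
              "bit_depth must divide 8 for byte packing")
  for (s in subframes) {
    stop_if_not(is.matrix(s) && all(s >= 0) && all(s <= spec$max_grey) &&
                  all(s == floor(s)),
                "subframes must be integer matrices in 0..%d", spec$max_grey)
  }
  # byte order B,R,G: bits [0,8) -> B, [8,16) -> R, [16,24) -> G
  byte_of <- c("B", "R", "G")
  lapply(seq_len(length(subframes) / spf), function(k) {
    grp <- subframes[((k - 1) * spf + 1):(k * spf)]
    d <- dim(grp[[1]])
    out <- array(0L, dim = c(d[1], d[2], 3),
                 dimnames = list(NULL, NULL, c("R", "G", "B")))
    for (i in seq_len(spf)) {
      byte_idx <- (i - 1) %/% per_byte          # 0-based byte within word
      shift <- ((i - 1) %% per_byte) * spec$bit_depth
      ch <- byte_of[byte_idx + 1]
      out[, , ch] <- out[, , ch] + grp[[i]] * 2L^shift
    }
    storage.mode(out) <- "integer"
    out
  })
}

#' Unpack 24-bit video frames into greyscale subframes
#'
#' Inverse of [pack_video_frames()].
#'
#' @param frames List of `height x width x 3` integer arrays with channels
#'   named R, G, B.
#' @param spec A [display_spec()].
#' @return List of integer subframe matrices, in presentation order.
#' @export
unpack_video_frames <- function(frames, spec = display_spec()) {
  stopifnot(inherits(spec, "display_spec"), is.list(frames))
  spf <- spec$subframes_per_frame
  per_byte <- 8L %/% spec$bit_depth
  byte_of <- c("B", "R", "G")
  out <- vector("list", length(frames) * spf)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    stop_if_not(length(dim(fr)) == 3 && dim(fr)[3] == 3,
                "packed frames must be h x w x 3 arrays")
    for (i in seq_len(spf)) {
      byte_idx <- (i - 1) %/% per_byte
      shift <- ((i - 1) %% per_byte) * spec$bit_depth
      ch <- byte_of[byte_idx + 1]
      v <- (fr[, , ch, drop = FALSE] %/% 2L^shift) %% 2L^spec$bit_depth
      v <- matrix(as.integer(v), dim(fr)[1], dim(fr)[2])
      out[[(k - 1) * spf + i]] <- v
    }
  }
  out
}

#' Signed intensity contrast between object and background
#'
#' Difference of normalised intensities, `object - background`, spanning -1
#' (dark object on bright background) through 0 (luminance-matched) to +1
#' (bright object on dark background). The source protocol labels this scale
#' "Weber contrast"; the difference form is the only one consistent with all
#' three endpoints, since the classical Weber ratio diverges on a dark
#' background.
#'
#' @param object_intensity,background_intensity Intensities in \[0, 1\].
#' @return Contrast in \[-1, 1\].
#' @export
stimulus_contrast <- function(object_intensity, background_intensity) {
  stop_if_not(all(object_intensity >= 0 & object_intensity <= 1) &&
                all(background_intensity >= 0 & background_intensity <= 1),
              "intensities must lie in [0, 1]")
  object_intensity - background_intensity
}

#' Circular-dot trajectory for fast local-motion mapping
#'
#' A dot of `dot_diameter` deg revolves along a circular path of
#' `path_diameter` deg at `frequency` cycles per second for `n_cycles`
#' cycles, clockwise or counter-clockwise. The position angle psi(t) of the
#' dot centre on the path starts at `psi0` (0 = rightmost point of the path,
#' counter-clockwise positive) and the instantaneous motion direction is the
#' tangent: `psi + 90` deg for CCW, `psi - 90` deg for CW.
#'
#' @param direction `"CW"` or `"CCW"`.
#' @param sample_rate Sampling rate of the returned time series (Hz),
#'   typically the display's pattern rate.
#' @param dot_diameter,path_diameter Dot and path diameters (deg).
#' @param frequency Rotation frequency (cycles/s).
#' @param n_cycles Number of full cycles.
#' @param psi0 Starting position angle (deg).
#' @return An object of class `dot_trajectory` with fields `times` (s),
#'   `position_angle` and `motion_direction` (deg, wrapped to \[0, 360)),
#'   the generating parameters, and `duration = n_cycles / frequency`.
#' @export
make_dot_trajectory <- function(direction = c("CW", "CCW"), sample_rate,
                                dot_diameter = 7.6, path_diameter = 10.4,
                                frequency = 2, n_cycles = 10, psi0 = 0) {
  direction <- match.arg(direction)
  stop_if_not(is_number(frequency) && frequency > 0,
              "frequency must be positive")
  stop_if_not(is_number(sample_rate) && sample_rate > 0,
              "sample_rate must be positive")
  duration <- n_cycles / frequency
  n <- max(1L, round(duration * sample_rate))
  times <- (seq_len(n) - 1) / sample_rate
  s <- if (direction == "CCW") 1 else -1
  psi <- wrap360(psi0 + s * 360 * frequency * times)
  theta <- wrap360(psi + s * 90)
  structure(list(times = times, position_angle = psi,
                 motion_direction = theta, direction = direction,
                 dot_diameter = dot_diameter, path_diameter = path_diameter,
                 frequency = frequency, n_cycles = n_cycles, psi0 = psi0,
                 sample_rate = sample_rate, duration = duration),
            class = "dot_trajectory")
}

#' Evaluate a dot trajectory in closed form at arbitrary times
#'
#' @param traj A [make_dot_trajectory()] object.
#' @param t Times (s); may lie outside the recorded span (the angular signal
#'   is periodic).
#' @return A list with `position_angle` and `motion_direction` (deg).
#' @export
trajectory_angles <- function(traj, t) {
  stopifnot(inherits(traj, "dot_trajectory"))
  s <- if (traj$direction == "CCW") 1 else -1
  psi <- wrap360(traj$psi0 + s * 360 * traj$frequency * t)
  list(position_angle = psi, motion_direction = wrap360(psi + s * 90))
}

#' Grid schedule for receptive-field mapping with stationary squares
#'
#' One small square per grid location, presented for `on_duration` with
#' `gap_duration` of background between presentations, scanned row-major
#' from the top-left cell. Entry k (0-based) has onset `k * (on + gap)`.
#'
#' @param grid_shape Integer vector `(rows, cols)`.
#' @param square_size Side of each square (deg).
#' @param on_duration,gap_duration Presentation and inter-stimulus gap (s).
#' @return An object of class `grid_schedule`: a data.frame with columns
#'   `row`, `col`, `onset`, `offset` plus the geometry as attributes.
#' @examples
#' sch <- make_grid_schedule()
#' nrow(sch)                      # 400 presentations
#' max(sch$offset) + 0.05        # 60 s total span
#' @export
make_grid_schedule <- function(grid_shape = c(20, 20), square_size = 0.5,
                               on_duration = 0.100, gap_duration = 0.050) {
  stop_if_not(on_duration > 0 && gap_duration >= 0,
              "durations must be positive")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  stop_if_not(nr >= 1 && nc >= 1, "grid_shape must be >= 1 in each dim")
  k <- seq_len(nr * nc) - 1L
  df <- data.frame(
    row = k %/% nc + 1L,
    col = k %% nc + 1L,
    onset = k * (on_duration + gap_duration),
    offset = k * (on_duration + gap_duration) + on_duration
  )
  structure(df, class = c("grid_schedule", "data.frame"),
            grid_shape = c(nr, nc), square_size = square_size,
            on_duration = on_duration, gap_duration = gap_duration)
}

#' Angular coordinates of grid-schedule cell centres
#'
#' The grid is centred on (0, 0): azimuth grows with column, elevation is
#' dorsal-positive so it decreases with row (row 1 is the top of the grid).
#'
#' @param schedule A [make_grid_schedule()] object.
#' @return A list of vectors `azimuth` (per column) and `elevation` (per
#'   row), in degrees.
#' @export
grid_coordinates <- function(schedule) {
  stopifnot(inherits(schedule, "grid_schedule"))
  shp <- attr(schedule, "grid_shape"); sz <- attr(schedule, "square_size")
  list(azimuth = (seq_len(shp[2]) - (shp[2] + 1) / 2) * sz,
       elevation = ((shp[1] + 1) / 2 - seq_len(shp[1])) * sz)
}

# Map angular coordinates (az right-positive, el dorsal-positive, deg) to
# fractional pixel coordinates (row, col) on the display.
angles_to_pixels <- function(az, el, spec) {
  list(row = (spec$height + 1) / 2 - el / spec$degrees_per_pixel,
       col = (spec$width + 1) / 2 + az / spec$degrees_per_pixel)
}

#' Render a stimulus protocol into frame pairs plus a sync trace
#'
#' Rasterises a dot trajectory (one pattern frame per trajectory sample) or
#' a grid schedule (one frame per presentation) onto the display: object
#' pixels are encoded with the object command, everything else with the
#' background command. A square synchronisation patch in the display corner
#' alternates black and white on every pattern frame so that a photodiode
#' can align stimuli with electrophysiology.
#'
#' @param x A `dot_trajectory` or `grid_schedule`.
#' @param object,background [pol_pixel_command()]s for object and background.
#' @param spec A [display_spec()].
#' @param centre Angular position (azimuth, elevation) of the pattern centre
#'   on the display, deg.
#' @param sync_size Side of the sync patch in pixels.
#' @return A list with `frames` (list of `frame_pair`) and `sync` (0/1
#'   vector, one entry per frame).
#' @export
render_frames <- function(x, object, background, spec = display_spec(),
                          centre = c(0, 0), sync_size = 50) {
  UseMethod("render_frames")
}

render_one <- function(mask, object, background, spec, sync_on, sync_size) {
  intens <- matrix(background$intensity, spec$height, spec$width)
  dolp <- matrix(background$dolp, spec$height, spec$width)
  intens[mask] <- object$intensity
  dolp[mask] <- object$dolp
  sz <- min(sync_size, spec$height, spec$width)
  if (sz > 0) {  # bottom-left corner patch, non-polarised
    intens[(spec$height - sz + 1):spec$height, 1:sz] <- as.numeric(sync_on)
    dolp[(spec$height - sz + 1):spec$height, 1:sz] <- 0
  }
  encode_frame(intens, dolp, spec)
}

#' @export
render_frames.dot_trajectory <- function(x, object, background,
                                         spec = display_spec(),
                                         centre = c(0, 0), sync_size = 50) {
  r_path <- x$path_diameter / 2
  r_dot <- x$dot_diameter / 2
  reach <- sqrt(sum(centre^2)) + r_path + r_dot
  half_w <- spec$width / 2 * spec$degrees_per_pixel
  half_h <- spec$height / 2 * spec$degrees_per_pixel
  stop_if_not(abs(centre[1]) + r_path + r_dot <= half_w &&
                abs(centre[2]) + r_path + r_dot <= half_h,
              "dot path (reach %.1f deg) does not fit on the display", reach)
  rows <- matrix(seq_len(spec$height), spec$height, spec$width)
  cols <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  frames <- vector("list", length(x$times))
  sync <- integer(length(x$times))
  for (i in seq_along(x$times)) {
    az <- centre[1] + r_path * cosd(x$position_angle[i])
    el <- centre[2] + r_path * sind(x$position_angle[i])
    p <- angles_to_pixels(az, el, spec)
    mask <- (rows - p$row)^2 + (cols - p$col)^2 <=
      (r_dot / spec$degrees_per_pixel)^2
    sync[i] <- (i - 1) %% 2
    frames[[i]] <- render_one(mask, object, background, spec,
                              sync[i], sync_size)
  }
  list(frames = frames, sync = sync)
}

#' @export
render_frames.grid_schedule <- function(x, object, background,
                                        spec = display_spec(),
                                        centre = c(0, 0), sync_size = 50) {
  coords <- grid_coordinates(x)
  sz <- attr(x, "square_size")
  half_w <- spec$width / 2 * spec$degrees_per_pixel
  half_h <- spec$height / 2 * spec$degrees_per_pixel
  stop_if_not(max(abs(centre[1] + coords$azimuth)) + sz / 2 <= half_w &&
                max(abs(centre[2] + coords$elevation)) + sz / 2 <= half_h,
              "grid does not fit on the display")
  rows <- matrix(seq_len(spec$height), spec$height, spec$width)
  cols <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  half_px <- sz / 2 / spec$degrees_per_pixel
  frames <- vector("list", nrow(x))
  sync <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    az <- centre[1] + coords$azimuth[x$col[i]]
    el <- centre[2] + coords$elevation[x$row[i]]
    p <- angles_to_pixels(az, el, spec)
    mask <- abs(rows - p$row) <= half_px & abs(cols - p$col) <= half_px
    sync[i] <- (i - 1) %% 2
    frames[[i]] <- render_one(mask, object, background, spec,
                              sync[i], sync_size)
  }
  list(frames = frames, sync = sync)
}
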