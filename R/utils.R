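# Internal helpers shared across modules. Angles are degrees everywhere in the
# public API; radians appear only transiently inside trig calls.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cosd <- function(x) cos(deg2rad(x))
sind <- function(x) sin(deg2rad(x))

#' @noRd
atan2d <- function(y, x) rad2deg(atan2(y, x))

# Wrap angles into [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Wrap angles into (-180, 180]
wrap180 <- function(x) {
  w <- wrap360(x)
  ifelse(w > 180, w - 360, w)
}

# Wrap an axial (180-deg periodic) angle into (-90, 90]
wrap_axial <- function(x) {
  w <- ((x %% 180) + 180) %% 180
  ifelse(w > 90, w - 180, w)
}

# round() in R rounds half to even; greyscale quantisation uses
# round-half-away-from-zero so that dolp = 0.5 at full intensity splits 8/7.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Sample indices of the half-open time window [from, to) in a uniformly
# sampled series starting at t0. Window edges that fall within 1e-6 samples
# of a sample instant are snapped to it, so schedule times that are exact
# multiples of the sampling step are classified consistently despite
# floating-point representation error.
sample_window <- function(from, to, t0, sample_rate) {
  snap <- function(x) {
    r <- round(x)
    ifelse(abs(x - r) < 1e-6, r, x)
  }
  i0 <- ceiling(snap((from - t0) * sample_rate)) + 1
  i1 <- ceiling(snap((to - t0) * sample_rate))
  c(i0, i1)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Seed handling: functions that draw random numbers accept `seed = NULL`
# (use the session RNG) or an integer (reproducible, restores RNG state).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stop_if_not(is_number(seed), "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
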