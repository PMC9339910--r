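#' Four-angle polarimetric image stack
#'
#' Linear-intensity images acquired through an analyser at 0, 45, 90 and
#' 135 deg. Values must be camera-linear (no gamma, no brightening); the
#' Stokes estimators below assume it.
#'
#' @param I0,I45,I90,I135 Non-negative numeric matrices of identical shape.
#' @return An object of class `polarimetric_stack`.
#' @export
polarimetric_stack <- function(I0, I45, I90, I135) {
  imgs <- list(I0 = I0, I45 = I45, I90 = I90, I135 = I135)
  d <- dim(I0)
  for (nm in names(imgs)) {
    stop_if_not(is.matrix(imgs[[nm]]), "%s must be a matrix", nm)
    stop_if_not(all(dim(imgs[[nm]]) == d), "image shapes differ (%s)", nm)
    stop_if_not(all(imgs[[nm]] >= 0), "%s has negative intensities", nm)
  }
  structure(imgs, class = "polarimetric_stack")
}

#' Stokes parameters from a four-angle stack
#'
#' The standard four-angle estimators for linear polarisation:
#' \deqn{S_0 = (I_0 + I_{45} + I_{90} + I_{135}) / 2}
#' \deqn{S_1 = I_0 - I_{90}}
#' \deqn{S_2 = I_{45} - I_{135}}
#' Under noise the physical bound `S1^2 + S2^2 <= S0^2` can fail at single
#' pixels; violations are counted and flagged in the returned object, never
#' clipped.
#'
#' @param stack A [polarimetric_stack()].
#' @return An object of class `stokes_maps`: matrices `S0`, `S1`, `S2` and a
#'   logical matrix `physical` marking pixels satisfying the bound.
#' @export
compute_stokes <- function(stack) {
  stopifnot(inherits(stack, "polarimetric_stack"))
  S0 <- (stack$I0 + stack$I45 + stack$I90 + stack$I135) / 2
  S1 <- stack$I0 - stack$I90
  S2 <- stack$I45 - stack$I135
  structure(list(S0 = S0, S1 = S1, S2 = S2,
                 physical = S1^2 + S2^2 <= S0^2 * (1 + 1e-12)),
            class = "stokes_maps")
}

#' Angle of polarisation map
#'
#' `AoP = 0.5 * atan2(S2, S1)` in degrees, wrapped to (-90, 90]; 0 deg is
#' the analyser's 0-deg axis. Pixels where `S1 = S2 = 0` (no linear
#' polarisation) are undefined and returned as `NA`.
#'
#' @param S A [compute_stokes()] result.
#' @return Matrix of AoP values in degrees, `NA` where undefined.
#' @export
compute_aop <- function(S) {
  stopifnot(inherits(S, "stokes_maps"))
  aop <- wrap_axial(rad2deg(atan2(S$S2, S$S1)) / 2)
  aop[S$S1 == 0 & S$S2 == 0] <- NA_real_
  aop
}

#' Degree of linear polarisation map
#'
#' `DoLP = sqrt(S1^2 + S2^2) / S0`. Pixels with `S0` at or below `floor`
#' (near-dark) are masked to `NA`. Values above 1 can arise from noise and
#' are reported as-is (see `attr(, "n_over_unity")`), never clipped.
#'
#' @param S A [compute_stokes()] result.
#' @param floor Minimum `S0` treated as valid; default `1e-6 * max(S0)`.
#' @return Matrix of DoLP values, `NA` where masked.
#' @export
compute_dolp <- function(S, floor = NULL) {
  stopifnot(inherits(S, "stokes_maps"))
  if (is.null(floor)) floor <- 1e-6 * max(S$S0, 0)
  dolp <- sqrt(S$S1^2 + S$S2^2) / S$S0
  dolp[S$S0 <= floor] <- NA_real_
  attr(dolp, "n_over_unity") <- sum(dolp > 1, na.rm = TRUE)
  dolp
}

#' Synthesise a four-angle stack from scene polarisation maps
#'
#' Inverse of the analysis chain, used for round-trip validation. With
#' `S1 = S0 * dolp * cos(2 aop)` and `S2 = S0 * dolp * sin(2 aop)`, the
#' intensity through an ideal analyser at angle phi follows Malus's law for
#' partially polarised light: `I(phi) = (S0 + S1 cos 2phi + S2 sin 2phi)/2`.
#'
#' @param S0 Total-intensity matrix (>= 0).
#' @param dolp DoLP matrix in \[0, 1\].
#' @param aop AoP matrix (deg).
#' @return A [polarimetric_stack()] sampled at phi = 0, 45, 90, 135 deg.
#' @export
synthesize_stack <- function(S0, dolp, aop) {
  stop_if_not(all(dolp >= 0 & dolp <= 1), "dolp must lie in [0, 1]")
  stop_if_not(all(S0 >= 0), "S0 must be non-negative")
  S1 <- S0 * dolp * cosd(2 * aop)
  S2 <- S0 * dolp * sind(2 * aop)
  at <- function(phi) (S0 + S1 * cosd(2 * phi) + S2 * sind(2 * phi)) / 2
  polarimetric_stack(at(0), at(45), at(90), at(135))
}

#' Extract one Bayer channel from an RGGB mosaic
#'
#' Colour channels of a raw mosaic are kept separate (no demosaicing): each
#' channel is the 2x2-strided subsample at its RGGB offset, halving the
#' resolution. Offsets (row, col, 1-based): R = (1,1), G1 = (1,2),
#' G2 = (2,1), B = (2,2).
#'
#' @param mosaic Numeric matrix with even dimensions.
#' @param channel One of `"R"`, `"G1"`, `"G2"`, `"B"`.
#' @return Half-resolution matrix.
#' @export
extract_bayer_channel <- function(mosaic, channel = c("R", "G1", "G2", "B")) {
  channel <- match.arg(channel)
  stop_if_not(is.matrix(mosaic), "mosaic must be a matrix")
  stop_if_not(nrow(mosaic) %% 2 == 0 && ncol(mosaic) %% 2 == 0,
              "mosaic dimensions must be even")
  off <- switch(channel, R = c(1, 1), G1 = c(1, 2), G2 = c(2, 1), B = c(2, 2))
  mosaic[seq(off[1], nrow(mosaic), by = 2), seq(off[2], ncol(mosaic), by = 2),
         drop = FALSE]
}

#' DoLP-weighted AoP visualisation
#'
#' Renders the AoP map as hue (periodic over 180 deg) with pixel brightness
#' scaled by the DoLP, so weakly polarised pixels appear darker. DoLP is
#' clamped to \[0, 1\] for display only; masked (`NA`) pixels render black.
#'
#' @param aop AoP matrix (deg).
#' @param dolp DoLP matrix, same shape.
#' @return An `height x width x 3` array of RGB values in \[0, 1\].
#' @export
dolp_weighted_aop_image <- function(aop, dolp) {
  stop_if_not(all(dim(aop) == dim(dolp)), "aop and dolp shapes differ")
  hue <- (wrap_axial(aop) + 90) / 180
  val <- pmin(pmax(dolp, 0), 1)
  bad <- is.na(hue) | is.na(val)
  hue[bad] <- 0; val[bad] <- 0
  hue[hue >= 1] <- 0  # hue is periodic
  cols <- grDevices::hsv(h = hue, s = 1, v = val)
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(nrow(aop), ncol(aop), 3),
               dimnames = list(NULL, NULL, c("R", "G", "B")))
  out[, , 1] <- rgb["red", ]
  out[, , 2] <- rgb["green", ]
  out[, , 3] <- rgb["blue", ]
  out
}
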