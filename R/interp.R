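# Separable 2D interpolation and Gaussian smoothing shared by the
# receptive-field and vector-field modules.

#' Separable bicubic-spline interpolation of a gridded surface
#'
#' Interpolates `z` (rows indexed by `y`, columns by `x`) onto the grid
#' `(yout, xout)` by cubic-spline interpolation along rows then columns
#' (`stats::spline`, `method = "fmm"`). The sampled nodes are reproduced
#' exactly and data lying on a plane are reproduced exactly.
#'
#' @param x,y Strictly increasing coordinate vectors (length >= 2 each).
#' @param z Matrix of size `length(y) x length(x)`.
#' @param xout,yout Output coordinates (within or outside the input range;
#'   extrapolation uses the end cubics).
#' @return Matrix of size `length(yout) x length(xout)`.
#' @export
interp2_spline <- function(x, y, z, xout, yout) {
  stop_if_not(is.matrix(z) && nrow(z) == length(y) && ncol(z) == length(x),
              "z must be length(y) x length(x)")
  stop_if_not(all(diff(x) > 0) && all(diff(y) > 0),
              "x and y must be strictly increasing")
  interp1 <- function(xs, vs, xo) {
    if (length(xs) == 1) return(rep(vs, length(xo)))
    stats::spline(xs, vs, xout = xo, method = "fmm")$y
  }
  tmp <- t(apply(z, 1, function(row) interp1(x, row, xout)))
  if (length(xout) == 1) tmp <- matrix(tmp, nrow = nrow(z))
  out <- apply(tmp, 2, function(col) interp1(y, col, yout))
  matrix(out, nrow = length(yout), ncol = length(xout))
}

#' Gaussian smoothing of a gridded map
#'
#' Separable Gaussian convolution with standard deviation `sd` grid cells.
#' Near the edges the kernel is renormalised over its in-bounds support, so
#' a constant map stays constant. Smoothing with sd `s1` then `s2` is
#' equivalent (away from edges) to one pass with `sqrt(s1^2 + s2^2)`.
#'
#' @param map Numeric matrix.
#' @param sd Kernel standard deviation in grid cells.
#' @param radius Kernel truncation radius in cells (default `ceiling(4 sd)`).
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(map, sd = 1, radius = NULL) {
  stop_if_not(is.matrix(map) && all(is.finite(map)), "map must be finite")
  if (sd <= 0) return(map)
  if (is.null(radius)) radius <- ceiling(4 * sd)
  k <- exp(-((-radius):radius)^2 / (2 * sd^2))
  smooth1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - radius):min(n, i + radius)
      w <- k[j - i + radius + 1]
      out[i] <- sum(w * v[j]) / sum(w)
    }
    out
  }
  t(apply(apply(map, 2, smooth1), 1, smooth1))
}
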