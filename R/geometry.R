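#' Two-element differential array geometry
#'
#' Describes a pair of closely spaced omnidirectional microphones used as a
#' first-order differential array: element spacing \code{d}, speed of sound
#' \code{c}, and sample rate \code{fs}. The dimensionless delay ratio
#' \eqn{\rho = (d/c)/T_s} compares the acoustic travel time between the
#' elements with the sampling period \eqn{T_s = 1/f_s}; \eqn{\rho = 1} is the
#' ideal case in which the rear null of the forward cardioid sits exactly at
#' 180 degrees.
#'
#' @param d element spacing in metres.
#' @param c speed of sound in m/s.
#' @param fs sample rate in Hz.
#' @return An object of class \code{"array_geometry"} with fields \code{d},
#'   \code{c}, \code{fs}, \code{Ts} and \code{rho}. \code{rho} is always
#'   recomputed from \code{(d, c, fs)}.
#' @examples
#' geom <- array_geometry(d = 0.0106, c = 340, fs = 32000)
#' geom$rho
#' @export
array_geometry <- function(d = 0.0106, c = 340, fs = 32000) {
  stopifnot(is.numeric(d), is.numeric(c), is.numeric(fs), length(d) == 1L,
            length(c) == 1L, length(fs) == 1L)
  if (!is.finite(d) || d <= 0) stop("element spacing 'd' must be > 0")
  if (!is.finite(c) || c <= 0) stop("sound speed 'c' must be > 0")
  if (!is.finite(fs) || fs <= 0) stop("sample rate 'fs' must be > 0")
  g <- list(d = d, c = c, fs = fs, Ts = 1 / fs, rho = (d / c) * fs)
  class(g) <- "array_geometry"
  g
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "Two-element differential array: d = %.4g m, c = %.4g m/s, fs = %g Hz (rho = %.6g)\n",
    x$d, x$c, x$fs, x$rho))
  invisible(x)
}

#' Geometry with a prescribed delay ratio
#'
#' Convenience constructor that perturbs the sound speed so the delay ratio
#' \eqn{\rho} takes an exact requested value at the given spacing and sample
#' rate. Used to study null degradation when \eqn{\rho \neq 1}.
#'
#' @param rho requested delay ratio (> 0).
#' @param d element spacing in metres.
#' @param fs sample rate in Hz.
#' @return An \code{array_geometry} whose \code{rho} equals \code{rho}.
#' @export
geometry_with_rho <- function(rho, d = 0.0106, fs = 32000) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho), rho > 0)
  array_geometry(d = d, c = d * fs / rho, fs = fs)
}
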