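#' Forward cardioid beam of a first-order differential array
#'
#' Delay-and-subtract beamforming for a two-element array: the previous
#' sample of the second channel is subtracted from the current sample of the
#' first, \eqn{z_F(n) = x_1(n) - x_2(n-1)}. For a plane wave this yields a
#' cardioid pointing along the M2-to-M1 endfire direction (0 degrees) with a
#' null at 180 degrees when the delay ratio is 1.
#'
#' The output has the same length as the input; the first sample has no
#' one-sample history and is a startup transient, marked by the attribute
#' \code{n0} (index of the first valid sample, 1-based). Statistics must
#' honour \code{n0}.
#'
#' @param x1,x2 numeric sample sequences of equal length (>= 2), channel 1 and
#'   channel 2 of the same recording.
#' @return Numeric vector of beam samples with attribute \code{n0 = 2}.
#' @examples
#' forward_beam(c(1, 1, 1), c(1, 1, 1))   # zero for n >= 2
#' @export
forward_beam <- function(x1, x2) {
  check_beam_inputs(x1, x2)
  n <- length(x1)
  z <- x1 - c(0, x2[-n])
  attr(z, "n0") <- 2L
  z
}

#' Backward cardioid beam of a first-order differential array
#'
#' Mirror image of \code{\link{forward_beam}}: \eqn{z_B(n) = x_2(n) - x_1(n-1)}.
#' The resulting cardioid looks toward 180 degrees with its null at 0 degrees
#' (delay ratio 1), and captures an enhanced copy of any rear-half-plane
#' interference used by the null-steering canceller.
#'
#' @inheritParams forward_beam
#' @return Numeric vector of beam samples with attribute \code{n0 = 2}.
#' @export
backward_beam <- function(x1, x2) {
  check_beam_inputs(x1, x2)
  n <- length(x2)
  z <- x2 - c(0, x1[-n])
  attr(z, "n0") <- 2L
  z
}

check_beam_inputs <- function(x1, x2) {
  if (!is.numeric(x1) || !is.numeric(x2))
    stop("beam inputs must be numeric sample sequences")
  if (length(x1) != length(x2))
    stop("channel lengths differ (", length(x1), " vs ", length(x2), ")")
  if (length(x1) < 2L)
    stop("beamforming needs at least 2 samples")
  invisible(TRUE)
}

#' Forward and backward beams as a pair
#'
#' Computes both cardioid beams from a two-channel recording and bundles them
#' with the sample rate and first-valid-sample index, the form consumed by the
#' null-steering stage.
#'
#' @param x1,x2 numeric sample sequences of equal length, or a
#'   \code{stereo_recording} passed as \code{x1}.
#' @param fs sample rate in Hz (ignored when a recording is given).
#' @return An object of class \code{"beam_pair"}: list with \code{zF},
#'   \code{zB}, \code{fs}, \code{n0}.
#' @export
beam_pair <- function(x1, x2 = NULL, fs = NULL) {
  if (inherits(x1, "stereo_recording")) {
    fs <- x1$fs
    x2 <- x1$x2
    x1 <- x1$x1
  }
  if (is.null(fs)) stop("'fs' is required when passing raw sample sequences")
  zF <- forward_beam(x1, x2)
  zB <- backward_beam(x1, x2)
  out <- list(zF = as.numeric(zF), zB = as.numeric(zB), fs = fs, n0 = 2L)
  class(out) <- "beam_pair"
  out
}

#' @export
print.beam_pair <- function(x, ...) {
  cat(sprintf("Forward/backward cardioid beam pair: %d samples at %g Hz (n0 = %d)\n",
              length(x$zF), x$fs, x$n0))
  invisible(x)
}

# Complex spatio-temporal transfer functions of the two beams, with channel 2
# as the amplitude/phase reference. Their magnitudes equal the closed-form
# cardioid responses; the phases are forced by the time-domain definitions.
forward_response_complex <- function(f, theta, geom) {
  om <- 2 * pi * f / geom$fs
  exp(1i * om * geom$rho * cospi(theta / 180)) - exp(-1i * om)
}

backward_response_complex <- function(f, theta, geom) {
  om <- 2 * pi * f / geom$fs
  1 - exp(1i * om * (geom$rho * cospi(theta / 180) - 1))
}

#' Closed-form amplitude response of the forward beam
#'
#' Magnitude of the spatio-temporal response of the forward cardioid,
#' \eqn{|H_F(f,\theta)| = |2 \sin(\pi f (1 + \rho\cos\theta)/f_s)|}, for a
#' far-field plane wave of frequency \code{f} arriving from angle
#' \code{theta} (degrees, counter-clockwise from the M2-to-M1 endfire
#' direction).
#'
#' @param f frequency in Hz, within \code{[0, fs/2]} (vectorised).
#' @param theta arrival angle in degrees (vectorised).
#' @param geom an \code{\link{array_geometry}}.
#' @return Non-negative magnitudes (at most 2).
#' @examples
#' geom <- geometry_with_rho(1)
#' forward_response_mag(8000, 180, geom)  # rear null: 0
#' forward_response_mag(8000, 0, geom)    # 2 at fs/4 on axis
#' @export
forward_response_mag <- function(f, theta, geom) {
  check_freq(f, geom)
  abs(2 * sin(pi * f * (1 + geom$rho * cospi(theta / 180)) / geom$fs))
}

#' Closed-form amplitude response of the backward beam
#'
#' \eqn{|H_B(f,\theta)| = |2 \sin(\pi f (\rho\cos\theta - 1)/f_s)|}; mirror of
#' \code{\link{forward_response_mag}} about broadside for \eqn{\rho = 1}.
#'
#' @inheritParams forward_response_mag
#' @return Non-negative magnitudes (at most 2).
#' @export
backward_response_mag <- function(f, theta, geom) {
  check_freq(f, geom)
  abs(2 * sin(pi * f * (geom$rho * cospi(theta / 180) - 1) / geom$fs))
}

check_freq <- function(f, geom) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > geom$fs / 2))
    stop("frequency must lie in [0, fs/2] = [0, ", geom$fs / 2, "] Hz")
  invisible(TRUE)
}

#' Beam directivity pattern over a frequency/angle grid
#'
#' Evaluates the forward or backward cardioid amplitude response on a grid,
#' e.g. to render directivity patterns and study how the rear null degrades
#' when the delay ratio deviates from 1 (the null splits for \eqn{\rho > 1}
#' and becomes shallower for \eqn{\rho < 1}).
#'
#' @param freqs frequencies in Hz (non-empty).
#' @param angles angles in degrees (non-empty).
#' @param geom an \code{\link{array_geometry}}.
#' @param which \code{"forward"} or \code{"backward"}.
#' @return An object of class \code{"response_grid"}: list with \code{freqs},
#'   \code{angles} and the \code{length(freqs) x length(angles)} magnitude
#'   matrix \code{H}.
#' @export
beam_pattern <- function(freqs, angles, geom, which = c("forward", "backward")) {
  which <- match.arg(which)
  if (length(freqs) == 0L || length(angles) == 0L)
    stop("frequency and angle grids must be non-empty")
  fun <- if (which == "forward") forward_response_mag else backward_response_mag
  H <- outer(freqs, angles, function(f, th) fun(f, th, geom))
  grid <- list(freqs = freqs, angles = angles, H = H, which = which)
  class(grid) <- "response_grid"
  grid
}

#' @export
print.response_grid <- function(x, ...) {
  cat(sprintf("Response grid (%s): %d frequencies x %d angles, max |H| = %.4g\n",
              if (is.null(x$which)) "filter" else x$which,
              length(x$freqs), length(x$angles), max(x$H)))
  invisible(x)
}

#' Export a response grid as delimited text
#'
#' Writes one \code{(freq, angle, magnitude)} row per grid point.
#'
#' @param grid a \code{response_grid}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_response_grid <- function(grid, path) {
  stopifnot(inherits(grid, "response_grid"))
  df <- data.frame(
    freq = rep(grid$freqs, times = length(grid$angles)),
    angle = rep(grid$angles, each = length(grid$freqs)),
    magnitude = as.vector(grid$H))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
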