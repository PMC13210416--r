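# Adaptive multi-tap null-steering: interference-plus-noise statistics from
# labelled segments, the Wiener canceller, and the orthogonal noise-subspace
# beamformer bank.

#' Interference-plus-noise statistics from labelled segments
#'
#' Estimates, by exact sample averages over the labelled
#' interference-plus-noise index set, the backward-beam covariance
#' \eqn{\hat R_v = (1/Y)\sum z_B(n) z_B(n)^T}, the cross-correlation
#' \eqn{\hat r_v = (1/Y)\sum z_F(n-\delta) z_B(n)} between the delayed
#' forward beam and the backward tap vector, and the full
#' \eqn{(h+1)\times(h+1)} covariance \eqn{\hat C} of the stacked vector
#' \eqn{[z_F(n-\delta); z_B(n), \ldots, z_B(n-h+1)]}. Only samples whose
#' whole \code{h}-tap history lies inside one labelled segment (and past the
#' beams' startup transient) contribute, so no event energy leaks into the
#' estimates.
#'
#' @param beams a \code{\link{beam_pair}}.
#' @param noise_segments two-column matrix of 1-based inclusive
#'   \code{[start, end]} sample runs labelled as interference-plus-noise
#'   (e.g. \code{rec$labels$noise_segments}), or a logical mask over samples.
#' @param h filter length (number of backward-beam taps); must equal
#'   \code{2 * delta + 1}.
#' @param delta integer delay applied to the forward beam.
#' @return An object of class \code{"noise_stats"}: \code{Rv} (h x h),
#'   \code{rv} (length h), \code{C} ((h+1) x (h+1)), sample support \code{Y},
#'   \code{h}, \code{delta}.
#' @export
estimate_noise_stats <- function(beams, noise_segments, h, delta) {
  stopifnot(inherits(beams, "beam_pair"))
  h <- as.integer(h); delta <- as.integer(delta)
  if (h != 2L * delta + 1L)
    stop("configuration error: filter length must satisfy h = 2*delta + 1")
  n <- length(beams$zB)
  if (is.logical(noise_segments)) {
    stopifnot(length(noise_segments) == n)
    noise_segments <- mask_to_segments(noise_segments)
  }
  acc <- matrix(0, h + 1L, h + 1L)
  Y <- 0L
  n0 <- beams$n0
  for (i in seq_len(nrow(noise_segments))) {
    s <- max(noise_segments[i, 1], n0)
    e <- min(noise_segments[i, 2], n)
    if (e - s + 1L < h) next
    zb <- beams$zB[s:e]
    Zb <- stats::embed(zb, h)               # rows: zB(n), zB(n-1), ..., zB(n-h+1)
    nn <- (s + h - 1L):e                    # absolute sample indices
    zf <- beams$zF[nn - delta]
    G <- cbind(zf, Zb)
    acc <- acc + crossprod(G)
    Y <- Y + length(nn)
  }
  if (Y < h + 1L)
    stop("rank deficiency: only ", Y, " labelled samples for h = ", h,
         " taps (need at least h + 1)")
  if (Y < 10L * h)
    warning("sample support Y = ", Y, " is below 10*h; covariance estimates ",
            "may be unstable")
  C <- acc / Y
  C <- (C + t(C)) / 2
  out <- list(Rv = C[-1, -1, drop = FALSE], rv = C[1, -1], C = C,
              Y = Y, h = h, delta = delta)
  class(out) <- "noise_stats"
  out
}

#' @export
print.noise_stats <- function(x, ...) {
  cat(sprintf("Interference-plus-noise statistics: h = %d, delta = %d, Y = %d samples\n",
              x$h, x$delta, x$Y))
  invisible(x)
}

# Solve R w = b for a symmetric PSD sample covariance. Ill-conditioned
# systems (a risk for long filters on low-rank interference) get diagonal
# loading relative to the average tap power, and the conditioning is logged;
# well-conditioned systems are solved exactly.
solve_cov <- function(R, b, rel = 1e-10) {
  rc <- rcond(R)
  if (rc < 1e-10) {
    message("covariance solve: ill-conditioned (rcond = ",
            format(rc, digits = 3), "); diagonal loading applied")
    R <- R + diag(rel * sum(diag(R)) / nrow(R), nrow(R))
  }
  as.numeric(solve(R, b))
}

#' Wiener canceller weights
#'
#' Solves the Wiener--Hopf normal equations \eqn{w = R_v^{-1} r_v} on the
#' labelled interference-plus-noise statistics. The solution minimises the
#' residual power \eqn{(1/Y)\sum (z_F(n-\delta) - w^T z_B(n))^2} over the
#' training set. Near-singular covariances receive a small diagonal loading
#' (1e-10 of the mean tap power) before inversion, with a logged message.
#'
#' @param stats a \code{\link{noise_stats}} object.
#' @return Numeric weight vector of length \code{stats$h}.
#' @export
wiener_weights <- function(stats) {
  stopifnot(inherits(stats, "noise_stats"))
  solve_cov(stats$Rv, stats$rv)
}

#' Interference-subspace dimension from an eigenvalue profile
#'
#' Returns the smallest \code{r} such that the leading \code{r} eigenvalues
#' retain at least the fraction \code{zeta} of the total energy,
#' \eqn{\sum_{j \le r} \lambda_j \ge \zeta \sum_j \lambda_j}.
#'
#' @param eigvals non-negative eigenvalues in descending order.
#' @param zeta retained energy fraction, default 0.95.
#' @return Integer subspace dimension \code{r}.
#' @export
subspace_dim <- function(eigvals, zeta = 0.95) {
  if (length(eigvals) == 0L) stop("empty eigenvalue vector")
  tol <- 1e-12 * max(abs(eigvals), 0)
  if (any(eigvals < -tol)) stop("eigenvalues must be non-negative")
  eigvals <- pmax(eigvals, 0)
  if (is.unsorted(rev(eigvals))) stop("eigenvalues must be in descending order")
  total <- sum(eigvals)
  if (total == 0) stop("undefined subspace dimension: all eigenvalues are zero")
  as.integer(which(cumsum(eigvals) >= zeta * total)[1])
}

#' Orthogonal noise-subspace beamformer bank
#'
#' Eigendecomposes the stacked covariance \eqn{C} of
#' \eqn{[z_F(n-\delta); z_B(n..n-h+1)]}, splits its eigenvectors into the
#' interference subspace (leading \code{r} eigenvalues retaining fraction
#' \code{zeta} of the energy) and the noise subspace, and converts noise-
#' subspace eigenvectors into branch filter weights. Branch \code{q} uses the
#' \eqn{(h-q+2)}-th eigenvector (so branch 1 takes the smallest eigenvalue);
#' each eigenvector is normalised to a leading element of 1 and the branch
#' weight is the negated remainder, so the branch output
#' \eqn{e_q(n) = z_F(n-\delta) - w_q^T z_B(n)} equals the stacked inner
#' product with the normalised eigenvector. Because noise-subspace vectors
#' are orthogonal to the interference subspace, every branch annihilates the
#' directional interference while responding differently to other arrivals.
#'
#' The branch count is clipped with a warning to the constraint
#' \eqn{Q < h - r + 1}; eigenvectors whose leading element is numerically
#' zero cannot be normalised and are skipped (the next noise-subspace
#' eigenvector is used instead). A warning is issued when \eqn{h \le r + 5},
#' the design rule being that the filter length should exceed the
#' interference-subspace dimension by more than five taps.
#'
#' @param C symmetric positive semi-definite stacked covariance
#'   ((h+1) x (h+1)), or a \code{\link{noise_stats}} object.
#' @param Q requested number of branches (>= 1).
#' @param zeta retained energy fraction defining the interference subspace.
#' @param delta forward-beam delay to record in the bank (taken from the
#'   \code{noise_stats} object when one is supplied).
#' @return An object of class \code{"beamformer_bank"}: \code{eigvals},
#'   \code{eigvecs}, \code{r}, \code{zeta}, \code{Q} (granted), \code{weights}
#'   (list of h-vectors), \code{branch_eigvec} (eigenvector index per branch),
#'   \code{wiener} (Wiener weights from the same covariance), \code{h},
#'   \code{delta}.
#' @export
parallel_weights <- function(C, Q = 3, zeta = 0.95, delta = NULL) {
  if (inherits(C, "noise_stats")) {
    delta <- C$delta
    C <- C$C
  }
  stopifnot(is.matrix(C), nrow(C) == ncol(C), Q >= 1)
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C), 1))
    stop("C must be symmetric")
  h <- nrow(C) - 1L
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors
  # sign convention: largest-magnitude element of each eigenvector positive
  for (j in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  r <- subspace_dim(vals, zeta)
  if (h <= r + 5L)
    warning("filter length h = ", h, " does not exceed the interference ",
            "subspace dimension r = ", r, " by more than 5 taps; consider ",
            "a longer filter")
  Qmax <- h - r                      # constraint Q < h - r + 1
  Q <- as.integer(Q)
  if (Q > Qmax) {
    Qgrant <- max(1L, Qmax)
    warning("branch count Q = ", Q, " violates Q < h - r + 1 (r = ", r,
            "); clipped to ", Qgrant)
    Q <- Qgrant
  }
  weights <- vector("list", Q)
  branch_eigvec <- integer(Q)
  cand <- h + 1L                     # start from the smallest eigenvalue
  for (q in seq_len(Q)) {
    repeat {
      if (cand <= r)
        stop("noise subspace exhausted while building branch ", q,
             " (degenerate leading elements)")
      u <- vecs[, cand]
      if (abs(u[1]) >= 1e-8 * sqrt(sum(u^2))) break
      message("branch construction: eigenvector ", cand,
              " has a degenerate leading element; skipped")
      cand <- cand - 1L
    }
    u <- vecs[, cand]
    wfb <- u / u[1]
    weights[[q]] <- -wfb[-1]
    branch_eigvec[q] <- cand
    cand <- cand - 1L
  }
  wiener <- solve_cov(C[-1, -1, drop = FALSE], C[1, -1])
  bank <- list(eigvals = vals, eigvecs = vecs, r = r, zeta = zeta, Q = Q,
               weights = weights, branch_eigvec = branch_eigvec,
               wiener = wiener, h = h, delta = delta)
  class(bank) <- "beamformer_bank"
  bank
}

#' @export
print.beamformer_bank <- function(x, ...) {
  cat(sprintf(
    "Null-steering beamformer bank: h = %d, delta = %s, r = %d (zeta = %g), Q = %d branches\n",
    x$h, if (is.null(x$delta)) "?" else x$delta, x$r, x$zeta, x$Q))
  cat("  eigenvalue range: [", format(min(x$eigvals), digits = 4), ", ",
      format(max(x$eigvals), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Apply a null-steering filter to a beam pair
#'
#' Computes the canceller output
#' \eqn{e(n) = z_F(n-\delta) - \sum_{m=0}^{h-1} w_{m+1} z_B(n-m)}. The first
#' \code{h + delta} samples lack full history and are zeroed as startup
#' transients (attribute \code{n0} marks the first valid sample).
#'
#' @param beams a \code{\link{beam_pair}}.
#' @param w weight vector of length \code{h = 2*delta + 1}.
#' @param delta integer forward-beam delay.
#' @return Numeric vector, same length as the beams, with attribute
#'   \code{n0 = h + delta + 1}.
#' @export
apply_filter <- function(beams, w, delta) {
  stopifnot(inherits(beams, "beam_pair"))
  h <- length(w)
  delta <- as.integer(delta)
  if (h != 2L * delta + 1L)
    stop("invalid input: length(w) must equal 2*delta + 1")
  n <- length(beams$zB)
  est <- stats::filter(beams$zB, w, method = "convolution", sides = 1)
  e <- shift_int(beams$zF, delta) - as.numeric(est)
  trans <- min(n, h + delta)
  e[seq_len(trans)] <- 0
  attr(e, "n0") <- trans + 1L
  e
}

#' Spatio-temporal response surface of a null-steering filter
#'
#' Evaluates \eqn{|E(f,\theta)| = |H_F(f,\theta) e^{-j2\pi f\delta/f_s} -
#' W(e^{j2\pi f/f_s}) H_B(f,\theta)|} over a frequency/angle grid, where
#' \eqn{H_F, H_B} are the complex beam transfer functions (channel 2 as
#' reference) and \eqn{W} is the filter's frequency response. A well-trained
#' filter shows a continuous groove along the interference's
#' frequency-by-angle support.
#'
#' @param w weight vector (length \code{2*delta + 1}).
#' @param delta integer forward-beam delay.
#' @param geom an \code{\link{array_geometry}}.
#' @param freqs frequencies in Hz.
#' @param angles angles in degrees.
#' @param normalize if \code{TRUE}, scale the surface to unit maximum.
#' @return A \code{response_grid} (\code{length(freqs) x length(angles)}
#'   magnitudes).
#' @export
bank_response_surface <- function(w, delta, geom, freqs, angles,
                                  normalize = FALSE) {
  if (length(freqs) == 0L || length(angles) == 0L)
    stop("frequency and angle grids must be non-empty")
  check_freq(freqs, geom)
  m <- seq_along(w) - 1
  H <- matrix(0, length(freqs), length(angles))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    om <- 2 * pi * f / geom$fs
    W <- sum(w * exp(-1i * om * m))
    hf <- forward_response_complex(f, angles, geom)
    hb <- backward_response_complex(f, angles, geom)
    H[i, ] <- Mod(hf * exp(-1i * om * delta) - W * hb)
  }
  if (normalize && max(H) > 0) H <- H / max(H)
  grid <- list(freqs = freqs, angles = angles, H = H, which = "filter")
  class(grid) <- "response_grid"
  grid
}

#' Serialize a beamformer bank to JSON
#'
#' @param bank a \code{\link{beamformer_bank}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "beamformer_bank"))
  obj <- list(h = bank$h, delta = bank$delta, zeta = bank$zeta, r = bank$r,
              Q = bank$Q, eigvals = bank$eigvals,
              weights = lapply(bank$weights, as.numeric),
              wiener = as.numeric(bank$wiener))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
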