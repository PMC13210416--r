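# Power spectrograms, frequency-dependent (CFAR-style) thresholds, binary
# spectrograms, sub-band entropy indices (FADI), and the OR-fusion
# compensated index (BIC-FADI).

#' Spectrogram analysis parameters
#'
#' Non-overlapping Hanning-tapered frames (frame length equals hop), with the
#' one-sided power spectrum truncated at \code{fmax}. With the defaults
#' (100 ms frames at 32 kHz, 12 kHz ceiling) each frame yields
#' \code{K = 1200} bins of width 10 Hz, and 60 s of audio gives
#' \code{L = 600} frames.
#'
#' @param fs sample rate in Hz.
#' @param frame_len frame (and hop) length in seconds.
#' @param fmax analysis ceiling in Hz (bins at or above it are discarded).
#' @return An object of class \code{"spectrogram_params"}: \code{fs},
#'   \code{frame_len}, \code{nfft} (samples per frame), \code{df} (bin width
#'   Hz), \code{K} (retained bins), \code{fmax}.
#' @export
spectrogram_params <- function(fs = 32000, frame_len = 0.1, fmax = 12000) {
  nfft <- as.integer(round(frame_len * fs))
  if (nfft < 2L) stop("frame too short")
  df <- fs / nfft
  K <- as.integer(round(fmax / df))
  if (K < 1L || K > nfft %/% 2L + 1L)
    stop("fmax must lie within (0, fs/2]")
  p <- list(fs = fs, frame_len = frame_len, nfft = nfft, df = df, K = K,
            fmax = fmax)
  class(p) <- "spectrogram_params"
  p
}

hanning_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Power spectrogram by short-time Fourier transform
#'
#' Splits the signal into non-overlapping Hanning-tapered frames, takes the
#' squared magnitude of the one-sided spectrum, and discards bins at or above
#' \code{fmax}. Row \code{k} (1-based) corresponds to physical frequency
#' \code{(k-1) * df}.
#'
#' @param x numeric sample sequence (at least one frame long).
#' @param fs sample rate in Hz.
#' @param params a \code{\link{spectrogram_params}}; built from \code{fs} if
#'   missing.
#' @return An object of class \code{"power_spectrogram"}: \code{P}
#'   (\code{K x L} matrix), \code{params}, \code{freqs}.
#' @export
stft_power <- function(x, fs, params = spectrogram_params(fs)) {
  n <- length(x)
  N <- params$nfft
  L <- n %/% N
  if (L < 1L) stop("invalid input: signal shorter than one frame")
  M <- matrix(x[seq_len(L * N)], nrow = N)
  M <- M * hanning_window(N)
  S <- stats::mvfft(M)
  P <- Mod(S[seq_len(params$K), , drop = FALSE])^2
  out <- list(P = P, params = params,
              freqs = (seq_len(params$K) - 1) * params$df)
  class(out) <- "power_spectrogram"
  out
}

#' @export
print.power_spectrogram <- function(x, ...) {
  cat(sprintf("Power spectrogram: K = %d bins (df = %g Hz) x L = %d frames\n",
              nrow(x$P), x$params$df, ncol(x$P)))
  invisible(x)
}

#' Single (global) detection threshold
#'
#' The conventional acoustic-diversity-index threshold: the spectrogram
#' maximum over bins at or above the low-frequency cutoff \code{kL}, divided
#' by \code{epsilon} (i.e. a fixed level below the peak).
#'
#' @param P a \code{\link{stft_power}} spectrogram.
#' @param epsilon peak-to-threshold power ratio (default 1e5, i.e. 50 dB).
#' @param kL 1-based index of the lowest bin considered (default 20, which is
#'   200 Hz at 10 Hz bins).
#' @return Scalar threshold \eqn{\eta_1}.
#' @export
single_threshold <- function(P, epsilon = 1e5, kL = 20) {
  stopifnot(inherits(P, "power_spectrogram"))
  K <- nrow(P$P)
  if (kL < 1L || kL > K) stop("kL out of range")
  max(P$P[kL:K, , drop = FALSE]) / epsilon
}

#' Per-bin noise level
#'
#' Time average of an interference-plus-noise power spectrogram in each
#' frequency bin, \eqn{Q_v(k) = (1/L) \sum_l P_v(k,l)}; the basis of the
#' floating (CFAR-style) threshold.
#'
#' @param Pv a \code{\link{stft_power}} spectrogram of interference-plus-noise
#'   material, or a plain K x L matrix.
#' @return Numeric vector of length K.
#' @export
noise_level <- function(Pv) {
  M <- if (inherits(Pv, "power_spectrogram")) Pv$P else Pv
  rowMeans(M)
}

#' Frequency-dependent threshold specification
#'
#' Combines the global threshold \eqn{\eta_1} with the floating per-bin
#' threshold \eqn{\eta_2(k) = \gamma_1 Q_v(k)}:
#' \eqn{\eta(k) = \max(\eta_1, \eta_2(k))}. \eqn{\gamma_1} is the minimum
#' SINR (linear power factor) a time-frequency point must clear above the
#' local noise level.
#'
#' @param P the signal spectrogram (used for \eqn{\eta_1}).
#' @param Qv per-bin noise level vector (see \code{\link{noise_level}}).
#' @param epsilon,kL parameters of \code{\link{single_threshold}}.
#' @param gamma1 floating-threshold factor (linear; default 20, i.e. 13 dB).
#' @return An object of class \code{"threshold_spec"} with fields
#'   \code{epsilon}, \code{kL}, \code{gamma1}, \code{Qv}, \code{eta1},
#'   \code{eta2}, \code{eta}.
#' @export
threshold_spec <- function(P, Qv, epsilon = 1e5, kL = 20, gamma1 = 20) {
  stopifnot(inherits(P, "power_spectrogram"), length(Qv) == nrow(P$P))
  eta1 <- single_threshold(P, epsilon, kL)
  eta2 <- gamma1 * Qv
  spec <- list(epsilon = epsilon, kL = kL, gamma1 = gamma1, Qv = Qv,
               eta1 = eta1, eta2 = eta2, eta = pmax(eta1, eta2))
  class(spec) <- "threshold_spec"
  spec
}

#' Binarize a power spectrogram
#'
#' Marks the time-frequency points whose power strictly exceeds the
#' frequency-dependent threshold \eqn{\eta(k)}.
#'
#' @param P a \code{\link{stft_power}} spectrogram.
#' @param spec a \code{\link{threshold_spec}} (or a numeric vector of per-bin
#'   thresholds).
#' @return An object of class \code{"binary_spectrogram"}: \code{G}
#'   (\code{K x L} 0/1 matrix) and \code{params}.
#' @export
binarize <- function(P, spec) {
  stopifnot(inherits(P, "power_spectrogram"))
  eta <- if (inherits(spec, "threshold_spec")) spec$eta else as.numeric(spec)
  if (length(eta) == 1L) eta <- rep(eta, nrow(P$P))
  stopifnot(length(eta) == nrow(P$P))
  G <- (P$P > eta) * 1L
  storage.mode(G) <- "integer"
  out <- list(G = G, params = P$params)
  class(out) <- "binary_spectrogram"
  out
}

#' @export
print.binary_spectrogram <- function(x, ...) {
  cat(sprintf("Binary spectrogram: %d x %d, %d active points (%.3g%%)\n",
              nrow(x$G), ncol(x$G), sum(x$G),
              100 * mean(x$G)))
  invisible(x)
}

#' Sub-band occupancy counts
#'
#' Partitions the analysis bandwidth into \code{I} contiguous sub-bands of
#' width \code{B} Hz and counts the active points of a binary spectrogram in
#' each: bin \code{k} (1-based, physical frequency \code{(k-1)*df}) belongs
#' to sub-band \code{i} when \code{(i-1)*B <= (k-1)*df < i*B}.
#'
#' @param G a \code{\link{binarize}}d spectrogram.
#' @param I number of sub-bands (default 12).
#' @param B sub-band width in Hz (default 1000).
#' @return Integer vector \code{N_i} of length \code{I}.
#' @export
subband_counts <- function(G, I = 12, B = 1000) {
  stopifnot(inherits(G, "binary_spectrogram"))
  df <- G$params$df
  k <- seq_len(nrow(G$G))
  band <- floor((k - 1) * df / B) + 1
  keep <- band >= 1 & band <= I
  rs <- rowSums(G$G)
  counts <- vapply(seq_len(I), function(i) sum(rs[keep & band == i]), numeric(1))
  as.integer(counts)
}

#' Sub-band entropy index
#'
#' Shannon entropy of the normalised sub-band occupancy distribution,
#' \eqn{-\sum_i p_i \ln(p_i + \xi)} with \eqn{p_i = N_i / \sum_j N_j}. An
#' empty binary spectrogram (\eqn{\sum_i N_i = 0}) has no defined
#' distribution; the result is then flagged undefined (value \code{NA}),
#' deliberately distinct from a numeric 0 (all mass in one band).
#'
#' @param counts per-sub-band occupancy counts.
#' @param xi small positive constant guarding the logarithm (default 1e-7).
#' @return An object of class \code{"index_result"}: \code{value},
#'   \code{counts}, \code{probs}, \code{I}, \code{xi}, \code{defined}.
#' @export
entropy_index <- function(counts, xi = 1e-7) {
  I <- length(counts)
  total <- sum(counts)
  if (total == 0) {
    message("entropy index undefined: empty binary spectrogram (no active points)")
    res <- list(value = NA_real_, counts = counts, probs = rep(NA_real_, I),
                I = I, xi = xi, defined = FALSE)
  } else {
    p <- counts / total
    res <- list(value = -sum(p * log(p + xi)), counts = counts, probs = p,
                I = I, xi = xi, defined = TRUE)
  }
  class(res) <- "index_result"
  res
}

#' @export
print.index_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Acoustic diversity index: %.5f (I = %d sub-bands, %d points)\n",
                x$value, x$I, sum(x$counts)))
  } else {
    cat("Acoustic diversity index: undefined (empty binary spectrogram)\n")
  }
  invisible(x)
}

#' Point-wise OR fusion of binary spectrograms
#'
#' Fuses branch binary spectrograms with a logical OR: a point is active in
#' the fused spectrogram when any branch detects it. This is the signal
#' compensation step: grooves shared by all branches (the interference
#' support) stay empty, while target detections lost to self-cancellation in
#' one branch are recovered from another.
#'
#' @param G_list list of \code{\link{binarize}}d spectrograms of identical
#'   shape.
#' @return A fused \code{binary_spectrogram}.
#' @export
or_fuse <- function(G_list) {
  stopifnot(length(G_list) >= 1L,
            all(vapply(G_list, inherits, logical(1), "binary_spectrogram")))
  dims <- vapply(G_list, function(g) dim(g$G), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("binary spectrograms must have identical shapes")
  G <- Reduce(function(a, b) pmax(a, b), lapply(G_list, `[[`, "G"))
  storage.mode(G) <- "integer"
  out <- list(G = G, params = G_list[[1]]$params)
  class(out) <- "binary_spectrogram"
  out
}

# Frames of an L-frame spectrogram that lie entirely inside the labelled
# noise segments (two-column 1-based inclusive sample matrix).
noise_frames <- function(segments, n_samples, params, L) {
  mask <- segments_to_mask(segments, n_samples)
  N <- params$nfft
  colSums(matrix(mask[seq_len(L * N)], nrow = N)) == N
}

#' Frequency-dependent acoustic diversity index (FADI)
#'
#' Full single-channel pipeline: power spectrogram, global plus floating
#' per-bin thresholds, binarization, sub-band counting, entropy. The
#' floating threshold's per-bin noise level is estimated either from a
#' separate interference-plus-noise reference signal or from the frames of
#' \code{x} that fall entirely inside labelled noise segments. Both
#' thresholds are homogeneous in the input power, so the index is invariant
#' to a global gain applied to \code{x} and the reference together.
#'
#' @param x numeric sample sequence (the recording, single channel).
#' @param fs sample rate in Hz.
#' @param noise either a numeric interference-plus-noise reference signal, or
#'   a two-column 1-based inclusive segment matrix interpreted on \code{x}.
#' @param params a \code{\link{spectrogram_params}}.
#' @param epsilon,kL,gamma1 threshold parameters (see
#'   \code{\link{threshold_spec}}).
#' @param I,B,xi sub-band and entropy parameters (see
#'   \code{\link{subband_counts}}, \code{\link{entropy_index}}).
#' @return An \code{\link{entropy_index}} result, with the binary spectrogram
#'   in \code{$G} and the threshold specification in \code{$thresholds}.
#' @export
fadi <- function(x, fs, noise, params = spectrogram_params(fs),
                 epsilon = 1e5, kL = 20, gamma1 = 20,
                 I = 12, B = 1000, xi = 1e-7) {
  P <- stft_power(x, fs, params)
  L <- ncol(P$P)
  if (is.matrix(noise) && !inherits(noise, "power_spectrogram")) {
    nf <- noise_frames(noise, length(x), params, L)
    if (!any(nf)) {
      warning("no spectrogram frame lies entirely inside the noise segments; ",
              "floating threshold disabled")
      Qv <- rep(0, nrow(P$P))
    } else {
      Qv <- rowMeans(P$P[, nf, drop = FALSE])
    }
  } else {
    Pv <- stft_power(as.numeric(noise), fs, params)
    Qv <- noise_level(Pv)
  }
  thr <- threshold_spec(P, Qv, epsilon, kL, gamma1)
  G <- binarize(P, thr)
  res <- entropy_index(subband_counts(G, I, B), xi)
  res$G <- G
  res$thresholds <- thr
  res
}

# Shared beamforming front end for the compensated index: beams, noise
# statistics, bank, branch outputs, per-branch thresholds and binaries.
bic_pipeline <- function(rec, config = default_config(), Q = config$Q,
                         with_wiener = TRUE) {
  stopifnot(inherits(rec, "stereo_recording"))
  if (is.null(rec$labels) || is.null(rec$labels$noise_segments) ||
      nrow(rec$labels$noise_segments) == 0L)
    stop("configuration error: labelled interference-plus-noise segments are required")
  params <- spectrogram_params(rec$fs, config$frame_len, config$fmax)
  beams <- beam_pair(rec)
  stats <- estimate_noise_stats(beams, rec$labels$noise_segments,
                                config$h, config$delta)
  bank <- parallel_weights(stats, Q = Q, zeta = config$zeta)
  n <- length(rec$x1)
  L <- n %/% params$nfft
  nf <- noise_frames(rec$labels$noise_segments, n, params, L)

  branch_binary <- function(w) {
    e <- apply_filter(beams, w, config$delta)
    P <- stft_power(as.numeric(e), rec$fs, params)
    Qv <- if (any(nf)) rowMeans(P$P[, nf, drop = FALSE]) else rep(0, nrow(P$P))
    binarize(P, threshold_spec(P, Qv, config$epsilon, config$kL, config$gamma1))
  }
  G_branches <- lapply(bank$weights, branch_binary)
  G_wiener <- if (with_wiener) branch_binary(bank$wiener) else NULL
  list(params = params, beams = beams, stats = stats, bank = bank,
       G_branches = G_branches, G_wiener = G_wiener)
}

#' Compensated acoustic diversity index (BIC-FADI)
#'
#' End-to-end two-channel pipeline: forward/backward cardioid beams, noise
#' statistics from the labelled interference-plus-noise segments, a bank of
#' \code{Q} orthogonal noise-subspace null-steering branches, per-branch
#' power spectrograms with per-branch thresholds (each branch's floating
#' threshold uses that branch's own output over the noise segments, matching
#' its spectral gain), per-branch binarization, point-wise OR fusion, and the
#' sub-band entropy index of the fused binary spectrogram.
#'
#' With \code{variant = "wiener"} the single Wiener canceller replaces the
#' bank (the uncompensated variant, one branch, no fusion gain).
#'
#' @param rec a \code{\link{render_scene}} recording, or any
#'   \code{stereo_recording} with labelled noise segments.
#' @param config a \code{\link{default_config}}-style parameter list.
#' @param Q number of bank branches to fuse.
#' @param variant \code{"bank"} (default) or \code{"wiener"}.
#' @return An \code{\link{entropy_index}} result with diagnostics: fused
#'   binary spectrogram \code{$G}, the \code{$bank}, and per-branch index
#'   values \code{$branch_values}.
#' @export
bic_fadi <- function(rec, config = default_config(), Q = config$Q,
                     variant = c("bank", "wiener")) {
  variant <- match.arg(variant)
  pipe <- bic_pipeline(rec, config, Q = Q, with_wiener = variant == "wiener")
  if (variant == "wiener") {
    G <- pipe$G_wiener
    branch_values <- NA_real_
  } else {
    G <- or_fuse(pipe$G_branches)
    branch_values <- vapply(pipe$G_branches, function(g) {
      r <- suppressMessages(entropy_index(subband_counts(g, config$I, config$B),
                                          config$xi))
      r$value
    }, numeric(1))
  }
  res <- entropy_index(subband_counts(G, config$I, config$B), config$xi)
  res$G <- G
  res$bank <- pipe$bank
  res$branch_values <- branch_values
  res
}

#' Ground-truth index of a synthetic scene
#'
#' The reference value a denoised pipeline should recover: the entropy index
#' of the binary spectrogram of the noise-free event mixture (channel 1),
#' computed with the same threshold rule. On a clean mixture the per-bin
#' noise level over the labelled noise segments is zero, so the global
#' threshold alone applies.
#'
#' @param rec a \code{\link{render_scene}} recording (carries the clean
#'   event mixture).
#' @param config parameter list.
#' @return An \code{\link{entropy_index}} result.
#' @export
ground_truth_fadi <- function(rec, config = default_config()) {
  stopifnot(inherits(rec, "stereo_recording"), !is.null(rec$clean1))
  params <- spectrogram_params(rec$fs, config$frame_len, config$fmax)
  fadi(rec$clean1, rec$fs, noise = rec$labels$noise_segments, params = params,
       epsilon = config$epsilon, kL = config$kL, gamma1 = config$gamma1,
       I = config$I, B = config$B, xi = config$xi)
}

#' All index variants of one recording
#'
#' Computes, sharing one beamforming front end: plain single-channel FADI of
#' channel 1; the Wiener-canceller variant; the compensated index for every
#' branch count in \code{Q_set} (cumulative OR fusion of the first q
#' branches); and, when the recording carries a clean event mixture, the
#' ground-truth index. If the subspace constraint grants fewer branches than
#' \code{max(Q_set)}, larger branch counts reuse the deepest available
#' fusion.
#'
#' @param rec a labelled \code{stereo_recording}.
#' @param config parameter list.
#' @param Q_set branch counts to evaluate (default 1 to 5).
#' @return Named list: \code{values} (named numeric: \code{FADI},
#'   \code{BIC-FADIw}, \code{BIC-FADI-q}..., \code{ground_truth}),
#'   \code{granted_Q}, \code{bank}.
#' @export
index_variants <- function(rec, config = default_config(), Q_set = 1:5) {
  Qmax <- max(Q_set)
  pipe <- suppressWarnings(bic_pipeline(rec, config, Q = Qmax,
                                        with_wiener = TRUE))
  granted <- pipe$bank$Q
  val <- function(G) {
    r <- suppressMessages(entropy_index(subband_counts(G, config$I, config$B),
                                        config$xi))
    r$value
  }
  params <- pipe$params
  f_plain <- fadi(rec$x1, rec$fs, noise = rec$labels$noise_segments,
                  params = params, epsilon = config$epsilon, kL = config$kL,
                  gamma1 = config$gamma1, I = config$I, B = config$B,
                  xi = config$xi)
  values <- c("FADI" = f_plain$value, "BIC-FADIw" = val(pipe$G_wiener))
  fused <- NULL
  fused_vals <- numeric(granted)
  for (q in seq_len(granted)) {
    fused <- if (is.null(fused)) pipe$G_branches[[1]] else
      or_fuse(list(fused, pipe$G_branches[[q]]))
    fused_vals[q] <- val(fused)
  }
  for (q in Q_set)
    values[paste0("BIC-FADI-", q)] <- fused_vals[min(q, granted)]
  if (!is.null(rec$clean1))
    values["ground_truth"] <- ground_truth_fadi(rec, config)$value
  list(values = values, granted_Q = granted, bank = pipe$bank)
}
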