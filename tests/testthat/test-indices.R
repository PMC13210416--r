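# Spectrograms, thresholds, binarization, sub-band entropy, fusion.

test_that("the STFT grid matches the canonical frame/bin layout", {
  # 60 s at 32 kHz with 100 ms frames and a 12 kHz ceiling: 1200 x 600
  p <- spectrogram_params(32000, 0.1, 12000)
  expect_equal(p$K, 1200L)
  expect_equal(p$df, 10)
  P <- stft_power(numeric(60 * 32000), 32000, p)
  expect_equal(dim(P$P), c(1200L, 600L))
  expect_true(all(P$P == 0))

  # a pure 1 kHz unit sinusoid peaks in the 1 kHz bin of every frame
  t <- (0:(32000 * 2 - 1)) / 32000
  P2 <- stft_power(sin(2 * pi * 1000 * t), 32000, p)
  expect_equal(dim(P2$P), c(1200L, 20L))
  peaks <- apply(P2$P, 2, which.max)
  expect_true(all(peaks == 101))               # (k-1)*10 Hz = 1000 -> k = 101

  expect_error(stft_power(numeric(10), 32000, p), "one frame")
})

test_that("the global threshold is a masked maximum over epsilon", {
  p <- spectrogram_params(1000, 0.064, 500)     # tiny grid for direct checks
  x <- sin(2 * pi * 100 * (0:639) / 1000)
  P <- stft_power(x, 1000, p)
  # direct evaluation against the masked-max oracle
  expect_equal(single_threshold(P, epsilon = 1e5, kL = 1),
               max(P$P) / 1e5)
  # homogeneity: scaling power scales the threshold
  P2 <- P; P2$P <- 3 * P$P
  expect_equal(single_threshold(P2, 1e5, 1), 3 * single_threshold(P, 1e5, 1))
  # energy below the cutoff bin is excluded from the maximum
  Pm <- P
  Pm$P[, ] <- 0.001
  Pm$P[2, 3] <- 50                              # below kL
  Pm$P[10, 1] <- 0.7
  expect_equal(single_threshold(Pm, 1e5, kL = 5), 0.7 / 1e5)
  expect_error(single_threshold(P, 1e5, kL = 0), "kL")
})

test_that("noise level is the per-bin time average", {
  set.seed(13)
  M <- matrix(rexp(20), 5, 4)
  expect_equal(noise_level(M), rowMeans(M))
  expect_equal(noise_level(matrix(2, 3, 7)), rep(2, 3))
  expect_equal(noise_level(matrix(c(1, 2, 3), 3, 1)), c(1, 2, 3))
})

test_that("binarization is an elementwise threshold comparison", {
  p <- spectrogram_params(1000, 0.008, 500)
  mk <- function(M) structure(list(P = M, params = p,
                                   freqs = (seq_len(nrow(M)) - 1) * p$df),
                              class = "power_spectrogram")
  P <- mk(matrix(c(10, 0.5), 1, 2))
  G <- binarize(P, 1)
  expect_equal(as.numeric(G$G), c(1, 0))
  # everything at or below threshold stays zero (strict inequality)
  expect_true(all(binarize(mk(matrix(1, 4, 3)), rep(1, 4))$G == 0))
  # random instance against the elementwise oracle
  set.seed(14)
  M <- matrix(runif(4 * 6), 4, 6)
  eta <- runif(4)
  G2 <- binarize(mk(M), eta)
  expect_equal(G2$G, (M > eta) * 1L, ignore_attr = TRUE)
})

test_that("sub-band counts follow the half-open frequency partition", {
  p <- spectrogram_params(32000, 0.1, 12000)
  mkG <- function(M) structure(list(G = M, params = p),
                               class = "binary_spectrogram")
  # all-ones 1200 x 600: each of 12 sub-bands holds 100 bins x 600 frames
  Gall <- mkG(matrix(1L, 1200, 600))
  expect_equal(subband_counts(Gall, 12, 1000), rep(60000L, 12))
  expect_equal(subband_counts(mkG(matrix(0L, 1200, 600)), 12, 1000),
               rep(0L, 12))
  # partition edges: k = 1 (0 Hz) belongs to the first band; k = 101
  # (1000 Hz) to the second
  M <- matrix(0L, 1200, 2)
  M[1, 1] <- 1L
  G1 <- mkG(M)
  expect_equal(subband_counts(G1, 12, 1000)[1], 1L)
  M2 <- matrix(0L, 1200, 2); M2[101, 1] <- 1L
  expect_equal(subband_counts(mkG(M2), 12, 1000)[2], 1L)
  M3 <- matrix(0L, 1200, 2); M3[100, 1] <- 1L   # 990 Hz: still band 1
  expect_equal(subband_counts(mkG(M3), 12, 1000)[1], 1L)
})

test_that("the entropy index matches closed forms and flags empty input", {
  # twelve equal counts: ln 12 up to the xi correction
  r <- entropy_index(rep(100, 12), xi = 1e-7)
  expect_equal(r$value, -12 * (1 / 12) * log(1 / 12 + 1e-7), tolerance = 1e-12)
  expect_equal(r$value, log(12), tolerance = 1e-4)
  expect_true(r$defined)
  # all mass in one band: -ln(1 + xi), essentially zero
  r1 <- entropy_index(c(0, 500, 0), 1e-7)
  expect_equal(r1$value, -log(1 + 1e-7), tolerance = 1e-15)
  # (3, 1) over two bands
  r2 <- entropy_index(c(3, 1), 1e-7)
  expect_equal(r2$value, -0.75 * log(0.75 + 1e-7) - 0.25 * log(0.25 + 1e-7),
               tolerance = 1e-12)
  expect_equal(r2$value, 0.5623, tolerance = 1e-4)
  expect_equal(sum(r2$probs), 1)
  # undefined sentinel, not zero
  expect_message(r0 <- entropy_index(rep(0, 12)), "undefined")
  expect_false(r0$defined)
  expect_true(is.na(r0$value))
  # bounds: 0 <= value <= ln(I) + I*xi for random nonempty counts
  set.seed(15)
  for (i in 1:25) {
    counts <- rpois(12, lambda = runif(1, 0.5, 50))
    if (sum(counts) == 0) counts[1] <- 1
    v <- entropy_index(counts)$value
    expect_gte(v, -log(1 + 1e-7))
    expect_lte(v, log(12) + 12 * 1e-7)
  }
})

test_that("OR fusion is the elementwise maximum and dominates every branch", {
  p <- spectrogram_params(32000, 0.1, 12000)
  mkG <- function(M) structure(list(G = M, params = p),
                               class = "binary_spectrogram")
  set.seed(16)
  Gs <- lapply(1:3, function(i) mkG(matrix(rbinom(200, 1, 0.3), 20, 10)))
  fused <- or_fuse(Gs)
  expect_equal(fused$G, Reduce(pmax, lapply(Gs, `[[`, "G")), ignore_attr = TRUE)
  for (g in Gs) expect_true(all(fused$G >= g$G))
  # identical inputs are a fixed point
  expect_equal(or_fuse(list(Gs[[1]], Gs[[1]]))$G, Gs[[1]]$G)
  # disjoint masks: union count equals the sum of counts
  A <- mkG(matrix(0L, 4, 4)); A$G[1, ] <- 1L
  B <- mkG(matrix(0L, 4, 4)); B$G[3, ] <- 1L
  expect_equal(sum(or_fuse(list(A, B))$G), sum(A$G) + sum(B$G))
  Gbad <- mkG(matrix(0L, 5, 4))
  expect_error(or_fuse(list(A, Gbad)), "shape")
})

test_that("FADI recovers the clean-scene index at high SINR without interference", {
  # 30-event protocol scene, interference disabled, SINR 30 dB
  spec <- experiment_one_spec("aerator_like", 30, 19)
  spec$target_inr_db <- -Inf
  rec <- render_scene(spec)
  cfg <- default_config()
  f <- fadi(rec$x1, rec$fs, noise = rec$labels$noise_segments,
            params = spectrogram_params(rec$fs, cfg$frame_len, cfg$fmax))
  gt <- ground_truth_fadi(rec, cfg)
  expect_true(f$defined && gt$defined)
  expect_lt(abs(f$value - gt$value), 0.05)
})

test_that("a recording identical to its noise reference yields a near-empty detection", {
  rec <- render_scene(scene_spec(NULL, "aerator_like", noise_seed = 37L,
                                 duration = 8))
  p <- spectrogram_params(rec$fs)
  res <- suppressMessages(
    fadi(rec$x1, rec$fs, noise = cbind(1L, length(rec$x1)), params = p))
  # only threshold exceedances by chance: a tiny fraction of the grid
  expect_lt(mean(res$G$G), 0.01)
})

test_that("indices are invariant to a global gain on recording and reference", {
  rec <- render_scene(small_scene_spec(sinr_db = 0, seed = 41L, duration = 8,
                                       n_events = 3L))
  p <- spectrogram_params(rec$fs)
  base <- fadi(rec$x1, rec$fs, noise = rec$labels$noise_segments, params = p)
  for (g in c(1e-3, 1e3)) {
    scaled <- fadi(g * rec$x1, rec$fs, noise = rec$labels$noise_segments,
                   params = p)
    expect_identical(scaled$G$G, base$G$G)
    expect_identical(scaled$value, base$value)
  }
})
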