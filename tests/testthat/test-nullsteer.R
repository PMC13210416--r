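# Noise statistics, Wiener solution, subspace split, bank construction,
# filtering, and response surfaces.

test_that("noise statistics are exact averages with the stacked layout", {
  # controlled beams: zF(n - delta) copies zB(n) exactly
  set.seed(2)
  n <- 5000
  zb <- rnorm(n)
  delta <- 2L; h <- 5L
  zf <- c(zb[(delta + 1):n], numeric(delta))   # zf[n - delta] == zb[n]
  beams <- fake_beam_pair(zf, zb)
  st <- estimate_noise_stats(beams, cbind(1L, n - delta), h, delta)
  expect_s3_class(st, "noise_stats")
  # rv must equal the first column of Rv by construction
  expect_equal(st$rv, st$Rv[, 1], tolerance = 1e-12)
  # C blocks: Rv is the trailing block, rv the first row restricted to it
  expect_equal(st$C[-1, -1], st$Rv)
  expect_equal(st$C[1, -1], st$rv)
  expect_true(isSymmetric(st$C))

  # independent white beams: Rv -> I, rv -> 0 at the LLN rate
  set.seed(3)
  n <- 60000
  beams2 <- fake_beam_pair(rnorm(n), rnorm(n))
  st2 <- estimate_noise_stats(beams2, cbind(1L, n), h, delta)
  tol <- 5 / sqrt(st2$Y)
  expect_lt(max(abs(st2$Rv - diag(h))), tol)
  expect_lt(max(abs(st2$rv)), tol)

  # zero inputs give zero statistics
  st0 <- estimate_noise_stats(fake_beam_pair(numeric(300), numeric(300)),
                              cbind(1L, 300L), h, delta)
  expect_equal(st0$C, matrix(0, h + 1, h + 1), ignore_attr = TRUE)

  expect_error(estimate_noise_stats(beams, cbind(1L, n), 5L, 1L),
               "h = 2\\*delta \\+ 1")
  expect_error(estimate_noise_stats(fake_beam_pair(numeric(8), numeric(8)),
                                    cbind(1L, 8L), 5L, 2L), "rank")
  expect_warning(estimate_noise_stats(fake_beam_pair(rnorm(40), rnorm(40)),
                                      cbind(1L, 40L), 5L, 2L), "support")
})

test_that("Wiener weights solve the normal equations and minimise residual power", {
  # h = 1 copy system: unit weight, zero residual
  set.seed(4)
  n <- 4000
  zb <- rnorm(n)
  beams <- fake_beam_pair(zb, zb)           # delta = 0: zF(n) = zB(n)
  st <- estimate_noise_stats(beams, cbind(1L, n), 1L, 0L)
  w <- wiener_weights(st)
  expect_equal(w, 1, tolerance = 1e-10)

  # rv = 0 gives w = 0
  st0 <- st
  st0$rv <- 0
  expect_equal(wiener_weights(st0), 0)

  # random 3-tap system against an explicit least-squares oracle
  set.seed(6)
  n <- 20000; h <- 3L; delta <- 1L
  zb <- as.numeric(arima.sim(list(ar = 0.6), n))
  zf <- as.numeric(stats::filter(zb, c(0.5, -0.2, 0.1), sides = 1))
  zf[is.na(zf)] <- 0
  zf <- c(zf[-(1:delta)], numeric(delta)) + rnorm(n, sd = 0.05)
  beams <- fake_beam_pair(zf, zb)
  seg <- cbind(10L, n - 10L)
  st <- estimate_noise_stats(beams, seg, h, delta)
  w <- wiener_weights(st)
  # oracle: brute-force least squares on the very same design rows
  s <- seg[1]; e <- seg[2]
  Zb <- embed(zb[s:e], h)
  y <- zf[((s + h - 1):e) - delta]
  w_ls <- qr.solve(Zb, y)
  expect_lt(max(abs(w - w_ls)), 1e-8)

  # optimality: no perturbed weight does better on the training quadratic
  J <- function(w) drop(t(c(1, -w)) %*% st$C %*% c(1, -w))
  j0 <- J(w)
  set.seed(7)
  for (i in 1:100) {
    d <- rnorm(h); d <- d / sqrt(sum(d^2)) * 0.01 * sqrt(sum(w^2))
    expect_gte(J(w + d), j0)
  }
})

test_that("subspace dimension follows the cumulative-energy rule", {
  expect_equal(subspace_dim(c(100, 1, 1, 1, 1), 0.95), 1L)   # 100/104 >= 0.95
  expect_equal(subspace_dim(rep(1, 20), 0.95), 19L)          # 19/20 = 0.95
  expect_equal(subspace_dim(5, 0.95), 1L)
  # random profiles against a cumulative-sum oracle
  set.seed(8)
  for (i in 1:20) {
    ev <- sort(rexp(12), decreasing = TRUE)
    zeta <- runif(1, 0.5, 0.999)
    expect_equal(subspace_dim(ev, zeta),
                 which(cumsum(ev) / sum(ev) >= zeta)[1])
  }
  expect_error(subspace_dim(numeric(3)), "zero")
  expect_error(subspace_dim(c(1, 2, 3)), "descending")
  expect_error(subspace_dim(c(3, -1)), "non-negative")
})

test_that("bank construction is orthonormal and handles degenerate leading elements", {
  # constructed spectrum: dominant direction with nonzero first element,
  # noise direction a with zero first element must be skipped
  b <- c(2, -1, -1) / sqrt(6)
  cc <- c(1, 1, 1) / sqrt(3)
  a <- c(0, 1, -1) / sqrt(2)
  C <- 100 * tcrossprod(b) + 2 * tcrossprod(cc) + 1 * tcrossprod(a)
  expect_message(bank <- suppressWarnings(parallel_weights(C, Q = 1, zeta = 0.95)),
                 "degenerate")
  expect_equal(bank$r, 1L)
  expect_equal(bank$branch_eigvec, 2L)            # skipped u3 = a, used u2 = cc
  expect_equal(bank$weights[[1]], c(-1, -1), tolerance = 1e-12)

  # a realistic random PSD matrix: orthonormal eigenvectors, valid quadratic
  # forms, and the spec'd branch-to-eigenvector assignment
  set.seed(9)
  h <- 9L
  A <- matrix(rnorm((h + 1)^2), h + 1)
  C2 <- crossprod(A) + diag(h + 1) * 0.01
  bank2 <- suppressWarnings(parallel_weights(C2, Q = 3, zeta = 0.95))
  G <- crossprod(bank2$eigvecs)
  expect_lt(max(abs(G - diag(h + 1))), 1e-10)
  # branch q built from eigenvector h - q + 2 (1 -> smallest eigenvalue)
  expect_equal(bank2$branch_eigvec[1], h + 1L)
  # norm-relative noise-subspace bound: wFB' C wFB <= lambda_{r+1} ||wFB||^2
  for (q in seq_len(bank2$Q)) {
    wfb <- c(1, -bank2$weights[[q]])
    expect_lte(drop(t(wfb) %*% C2 %*% wfb),
               bank2$eigvals[bank2$r + 1] * sum(wfb^2) * (1 + 1e-10))
  }
  # eigenvalues descending
  expect_true(all(diff(bank2$eigvals) <= 1e-12))
})

test_that("the branch-count constraint Q < h - r + 1 is enforced with a warning", {
  # rotated spectrum with r = h - 1: only one branch is admissible
  set.seed(10)
  h <- 5L
  V <- qr.Q(qr(matrix(rnorm((h + 1)^2), h + 1)))
  C <- V %*% diag(c(10, 8, 6, 4, 0.1, 0.05)) %*% t(V)
  expect_warning(expect_warning(bank <- parallel_weights(C, Q = 5, zeta = 0.95),
                                "clipped"),
                 "5 taps")                       # h <= r + 5 design-rule warning
  expect_lt(bank$Q, h - bank$r + 1)
})

test_that("apply_filter matches direct convolution and honours transients", {
  set.seed(11)
  n <- 400; h <- 5L; delta <- 2L
  zf <- rnorm(n); zb <- rnorm(n)
  beams <- fake_beam_pair(zf, zb)
  # zero weights / zero auxiliary channel: delayed forward beam passes through
  e0 <- apply_filter(beams, numeric(h), delta)
  expect_equal(as.numeric(e0[(h + delta + 1):n]), zf[(h + 1):(n - delta)])
  expect_equal(as.numeric(e0[1:(h + delta)]), numeric(h + delta))
  expect_equal(attr(e0, "n0"), h + delta + 1L)
  ez <- apply_filter(fake_beam_pair(zf, numeric(n)), rnorm(h), delta)
  expect_equal(as.numeric(ez[(h + delta + 1):n]), zf[(h + 1):(n - delta)])

  # random weights against a naive O(n*h) convolution oracle
  w <- rnorm(h)
  e <- apply_filter(beams, w, delta)
  oracle <- vapply((h + delta + 1):n, function(nn)
    zf[nn - delta] - sum(w * zb[nn - (0:(h - 1))]), numeric(1))
  expect_equal(as.numeric(e[(h + delta + 1):n]), oracle, tolerance = 1e-12)

  expect_error(apply_filter(beams, numeric(4), delta), "2\\*delta")
})

test_that("trained response surfaces groove along the interference support", {
  # events-free training scene: broadband interference at 150 deg, INR 40 dB
  rec <- render_scene(scene_spec(NULL, "aerator_like", 150, noise_seed = 23L,
                                 duration = 10))
  beams <- beam_pair(rec)
  cfg <- default_config()
  st <- estimate_noise_stats(beams, rec$labels$noise_segments, cfg$h, cfg$delta)
  w <- wiener_weights(st)
  geom <- rec$spec$geom
  freqs <- seq(1000, 12000, by = 250)
  angles <- seq(0, 359, by = 3)
  surf <- bank_response_surface(w, cfg$delta, geom, freqs, angles)
  support <- surf$H[, angles == 150]
  depth_db <- 20 * log10(mean(support) / max(surf$H))
  expect_lt(depth_db, -20)

  # w = 0, delta = 0 reduces to the forward beam magnitude response
  s0 <- bank_response_surface(0, 0, geom, c(2000, 7000), seq(0, 180, 5))
  expect_equal(s0$H,
               outer(c(2000, 7000), seq(0, 180, 5),
                     function(f, th) forward_response_mag(f, th, geom)),
               tolerance = 1e-12)

  # single-tap canceller: null angle drifts with frequency (no broadband
  # alignment), while the 21-tap surface grooves at 150 across the band.
  # Responses depend on angle only through cos(theta), so angles are folded
  # to [0, 180] before comparing null locations.
  fold <- function(a) pmin(a, 360 - a)
  st1 <- estimate_noise_stats(beams, rec$labels$noise_segments, 1L, 0L)
  w1 <- wiener_weights(st1)
  s1 <- bank_response_surface(w1, 0L, geom, freqs, angles)
  null_angle <- fold(angles[apply(s1$H, 1, which.min)])
  expect_gt(diff(range(null_angle)), 10)
  null21 <- fold(angles[apply(surf$H, 1, which.min)])
  expect_lt(max(abs(null21 - 150)), 15)
})

test_that("deep noise-subspace branches suppress interference and differ off-support", {
  rec <- render_scene(scene_spec(NULL, "aerator_like", 150, noise_seed = 29L,
                                 duration = 12))
  beams <- beam_pair(rec)
  cfg <- default_config()
  st <- estimate_noise_stats(beams, rec$labels$noise_segments, cfg$h, cfg$delta)
  bank <- suppressWarnings(parallel_weights(st, Q = 2, zeta = cfg$zeta))
  n <- length(beams$zF)
  sel <- (cfg$h + cfg$delta + 1):n
  pF <- mean(beams$zF[sel]^2)
  # the two deepest noise-subspace branches: scale-invariant suppression
  # (output of the unit-norm stacked filter, branch output times |u1|)
  # relative to the interference-dominated forward beam
  for (q in seq_len(bank$Q)) {
    e <- apply_filter(beams, bank$weights[[q]], cfg$delta)
    u1 <- bank$eigvecs[1, bank$branch_eigvec[q]]
    p_unit <- mean((e[sel] * abs(u1))^2)
    red_db <- 10 * log10(pF / p_unit)
    expect_gt(red_db, 20)
  }
  # diversity: distinct branch surfaces differ by >= 3 dB somewhere off-support
  freqs <- seq(1000, 12000, by = 500)
  angles <- seq(0, 120, by = 5)                  # away from the 150 deg support
  s1 <- bank_response_surface(bank$weights[[1]], cfg$delta, rec$spec$geom,
                              freqs, angles, normalize = TRUE)
  s2 <- bank_response_surface(bank$weights[[2]], cfg$delta, rec$spec$geom,
                              freqs, angles, normalize = TRUE)
  ratio_db <- 20 * abs(log10(pmax(s1$H, 1e-12) / pmax(s2$H, 1e-12)))
  expect_gt(max(ratio_db), 3)
})

test_that("banks serialize to JSON with their eigenstructure", {
  set.seed(12)
  A <- matrix(rnorm(36), 6)
  bank <- suppressWarnings(parallel_weights(crossprod(A) + diag(6), Q = 2,
                                            zeta = 0.9, delta = 2L))
  path <- tempfile(fileext = ".json")
  write_bank(bank, path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(obj$h, 5)
  expect_equal(obj$r, bank$r)
  expect_length(obj$weights, bank$Q)
  expect_equal(unlist(obj$weights[[1]]), bank$weights[[1]], tolerance = 1e-12)
})
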