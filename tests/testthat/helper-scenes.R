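# Shared fixtures, built in code. Short scenes keep unit tests fast; the
# full 60 s protocol scenes appear only in the acceptance tests.

# A compact labelled scene: `n_events` 0.1 s events in 2 s slots over
# `duration` seconds, interference at 150 deg, INR 40 dB.
small_scene_spec <- function(sinr_db = 0, seed = 11L, duration = 12,
                             n_events = 5L, background = "aerator_like",
                             angles = NULL, inr_db = 40) {
  ev <- with_seed_test(seed, {
    data.frame(onset = 2 * (seq_len(n_events) - 1) +
                 stats::runif(n_events, 0.05, 1.85),
               duration = 0.1,
               band_lo = 1000, band_hi = 12000,
               angle = if (is.null(angles))
                 stats::runif(n_events, 0, 180) else angles,
               seed = seed + 100L + seq_len(n_events))
  })
  scene_spec(ev, interference_kind = background, interference_angle = 150,
             noise_seed = seed, target_sinr_db = sinr_db,
             target_inr_db = inr_db, duration = duration)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Beam pair built directly from chosen beam signals (bypasses the array),
# for controlled statistics tests.
fake_beam_pair <- function(zF, zB, fs = 32000) {
  structure(list(zF = zF, zB = zB, fs = fs, n0 = 2L), class = "beam_pair")
}

# Configuration scaled to a short scene (keeps h, delta and thresholds).
short_config <- function(duration = 12) {
  cfg <- unclass(default_config())
  cfg$duration <- duration
  cfg$L <- as.integer(duration / cfg$frame_len)
  validate_config(cfg)
}
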