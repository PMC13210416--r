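# bicfadi

Denoising preprocessing for two-microphone passive acoustic monitoring
(PAM) in soundscapes dominated by a single directional anthropogenic
interference source — and the compensated acoustic diversity index built on
top of it.

## Who this is for

Ecoacousticians computing acoustic indices (rapid biodiversity assessment)
from stereo PAM recorders deployed in urban–rural areas, where a strong
broadband interferer (aquaculture aerators, agricultural drones, machinery)
sits in a known, narrow angular sector and masks avian vocalisations.
Single-channel fixes (high-pass filtering, frequency-dependent thresholds)
fail when the interference overlaps the birds in frequency; this package
implements the two-channel spatial-filtering alternative.

## What it computes

Two closely spaced omnidirectional microphones (spacing d, sound speed c,
sample rate fs) form a first-order differential array. Delay-and-subtract
gives back-to-back cardioid beams

    zF(n) = x1(n) − x2(n−1),   |HF(f,θ)| = |2 sin(π f (1 + ρ cosθ) / fs)|
    zB(n) = x2(n) − x1(n−1),   |HB(f,θ)| = |2 sin(π f (ρ cosθ − 1) / fs)|

with ρ = (d/c)·fs the delay ratio (ρ = 1 puts the forward null exactly at
180°). The forward beam is the main channel; an adaptive multi-tap
canceller estimates the interference residual from the last h backward-beam
samples and subtracts it:

    e(n) = zF(n−δ) − wᵀ zB(n),      h = 2δ + 1
    w_opt = Rv⁻¹ rv                  (Wiener–Hopf, statistics estimated by
                                      sample averages over labelled
                                      interference-plus-noise segments)

Beyond the single Wiener solution, the package eigendecomposes the
(h+1)×(h+1) covariance C of the stacked vector [zF(n−δ); zB(n..n−h+1)],
splits interference and noise subspaces at an energy fraction ζ (default
0.95, dimension r), and turns Q mutually orthogonal noise-subspace
eigenvectors into parallel null-steering branches (branch q uses
eigenvector h−q+2, normalised to a unit leading element). Every branch
forms a groove along the interference's frequency-by-angle support while
responding differently to bird events elsewhere.

Each branch output is binarised with the frequency-dependent (CFAR-style)
threshold η(k) = max(η₁, γ₁·Qv(k)) — η₁ the spectrogram peak over ε, Qv(k)
the per-bin noise level of that branch over the labelled segments — and the
branch binary spectrograms are fused by a point-wise logical OR. The Shannon
entropy of the fused sub-band occupancy (I = 12 bands of 1 kHz) is the
compensated index **BIC-FADI**; the same entropy without preprocessing is
the frequency-dependent acoustic diversity index (FADI).

A calibrated scene simulator (band-limited 0.1 s avian events, a directional
broadband interference stand-in, a pink-noise floor, exact SINR/INR control,
ground-truth labels) reproduces the simulation protocols end to end.

## Worked example

```r
library(bicfadi)

# 60 s scene: 30 events (20 at 0-90 deg, 10 at 150-180 deg), aerator-like
# interference at 150 deg, INR 40 dB, SINR -10 dB
rec <- render_scene(experiment_one_spec("aerator_like", sinr_db = -10, seed = 1))
rec
#> Stereo recording: 60 s at 32000 Hz, 30 events, SINR -10.00 dB, INR 40.00 dB, Y = 1822020 noise samples

res <- bic_fadi(rec, Q = 3)
res
#> Acoustic diversity index: 2.32508 (I = 12 sub-bands, 17077 points)

ground_truth_fadi(rec)$value
#> [1] 2.368691
fadi(rec$x1, rec$fs, noise = rec$labels$noise_segments)$value
#> entropy index undefined: empty binary spectrogram (no active points)
#> [1] NA
```

At −10 dB SINR the compensated index (2.325) sits close to the clean-scene
ground truth (2.369), while the raw single-channel FADI fails outright: the
broadband interference raises every per-bin threshold above the masked
events, the binary spectrogram comes out empty, and the index is reported
as an explicit *undefined* sentinel rather than a misleading number.

The command-line interface wraps the same functions
(`inst/cli/bicfadi.R`): `simulate`, `beamform`, `index`, `sweep`, `exp2`.

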