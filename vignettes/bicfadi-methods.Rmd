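---
title: "Null-steering beamformer bank preprocessing for acoustic diversity indices: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-steering beamformer bank preprocessing for acoustic diversity indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicfadi)
```

## The problem

Acoustic diversity indices summarise a soundscape recording into a single
number — here the Shannon entropy of how detected time–frequency activity
spreads across 1 kHz sub-bands — and are widely used for rapid biodiversity
assessment from passive acoustic monitoring. In urban–rural deployments a
single strong anthropogenic source (an aerator, a drone, farm machinery)
often radiates broadband noise from a narrow, roughly known angular sector.
Because it overlaps bird vocalisations in frequency, no single-channel
operation (high-pass filtering, per-bin thresholds) can remove it without
also removing birds; but because it is *directional*, a two-microphone
differential array can.

This package implements that preprocessing chain and the compensated index
on top of it, plus a calibrated scene simulator so the whole behaviour can
be studied without field recordings.

## Signal model and the differential beam pair

The recording is `x(n) = s(n) + φ(n) + v(n)`: biotic events `s`, a
spatially correlated directional interference `φ`, and spatially
uncorrelated noise `v`. For a far-field plane wave at angle θ
(counter-clockwise from the M2→M1 endfire axis) the two microphones differ
only by the travel-time delay τ = −d·cosθ/c. With the delay ratio
ρ = (d/c)·fs, delay-and-subtract yields the forward and backward cardioids

$$z_F(n) = x_1(n) - x_2(n-1), \qquad
  z_B(n) = x_2(n) - x_1(n-1),$$

with amplitude responses $|2\sin(\pi f(1+\rho\cos\theta)/f_s)|$ and
$|2\sin(\pi f(\rho\cos\theta-1)/f_s)|$. At ρ = 1 the forward null sits
exactly at 180° at every frequency; ρ < 1 (sound speed higher than assumed)
makes the null shallow, ρ > 1 splits it into two off-axis notches. Both
degradations are reproduced by `beam_pattern()` and motivate the adaptive
stage: a fixed cardioid null cannot be trusted in the field. The complex
transfer functions used for response surfaces are the ones forced by the
time-domain definitions (with channel 2 as phase reference):
$H_F = e^{j\omega\rho\cos\theta} - e^{-j\omega}$ and
$H_B = 1 - e^{j\omega(\rho\cos\theta - 1)}$, $\omega = 2\pi f/f_s$; their
magnitudes reduce to the closed forms above.

The beams also act as first-order differentiators (gain ∝ sin(πf/fs)),
which usefully suppresses low-frequency noise such as equipment self-noise
before any index is computed.

## Adaptive null steering and the beamformer bank

The canceller treats the forward beam as main channel and predicts its
interference content from the last `h` backward-beam samples:
`e(n) = zF(n−δ) − wᵀ zB(n)` with `h = 2δ + 1` so the filter is centred.
All second-order statistics are estimated as exact sample averages over
*labelled interference-plus-noise segments* — periods with no bird activity
(ground-truth labels from the simulator; auditory selection in field use).
Only samples whose full h-tap history lies inside one labelled segment
contribute, so event energy never leaks into the estimates. The Wiener
solution `w = Rv⁻¹ rv` minimises the training residual.

A single unconstrained canceller also nulls whatever else it can predict —
including birds near the interference direction (self-cancellation). The
bank addresses this: the (h+1)×(h+1) covariance `C` of the stacked vector
`[zF(n−δ); zB(n..n−h+1)]` is eigendecomposed, the leading eigenvalues
retaining the fraction ζ of total energy define the interference subspace
(dimension `r`), and branch `q` is built from eigenvector `h−q+2` (branch 1
from the smallest eigenvalue). Each eigenvector is scaled to a unit leading
element; the negated remainder is the branch's tap vector, so the branch
output is the stacked inner product with that eigenvector. Orthogonality to
the interference subspace makes every branch annihilate the interference;
mutual orthogonality makes their responses to everything else differ, which
is what the later fusion exploits. The branch count obeys `Q < h − r + 1`
(requests beyond it are clipped with a warning), and a configuration
warning fires when `h ≤ r + 5`: the filter should be at least five taps
longer than the interference subspace so the last few eigenvectors are
reliably noise-like.

### A note on branch normalisation and gain

The leading-element normalisation fixes the *shape* of each branch but not
a physically meaningful gain: an eigenvector whose leading element is small
(the vector lives mostly in the backward-tap space) yields large tap
weights and a branch output whose absolute power can exceed the forward
beam's, even though the branch still nulls the interference *relative to
its own gain*. Two consequences shape the design here:

* Suppression is therefore measured scale-invariantly: the output power of
  the *unit-norm* stacked filter (branch output times its leading element)
  against the forward-beam power. That quantity is bounded by the
  noise-subspace eigenvalues and is what the eigen construction actually
  guarantees.
* Every branch gets its *own* thresholds. Both the peak-referenced
  threshold η₁ and the per-bin floating threshold γ₁·Qv(k) are computed
  from that branch's spectrogram and its own output over the labelled
  segments, so an arbitrary branch gain (and the strongly frequency-
  dependent spectral shaping every branch applies) cancels out of the
  binarisation. A vector with a *numerically* zero leading element
  (|u₁| < 1e−8·‖u‖) cannot be normalised at all and is skipped for the
  next noise-subspace eigenvector, with a logged message.

Branches dominated by the backward taps behave like interference-nulled,
filtered backward beams: they favour arrivals from the rear half-plane.
That is precisely where the single Wiener canceller loses birds, so these
branches supply the complementary detections the fusion step needs.

## From branch outputs to the compensated index

Each output is framed into non-overlapping 100 ms Hanning-tapered frames;
one-sided power spectra are truncated at 12 kHz (K = 1200 bins of 10 Hz; a
60 s scene gives L = 600 frames). A time–frequency point is detected when
its power strictly exceeds η(k) = max(η₁, γ₁·Qv(k)); η₁ is the spectrogram
maximum over bins k ≥ kL divided by ε. Detections are counted in I = 12
sub-bands of B = 1 kHz (bin k, at physical frequency (k−1)·Δf, belongs to
band i when (i−1)B ≤ (k−1)Δf < iB), normalised to probabilities, and the
index is −Σ pᵢ ln(pᵢ + ξ).

The branch binary spectrograms are fused by point-wise logical OR before
counting: grooves shared by all branches (the interference support) stay
empty while detections lost to self-cancellation in one branch are
recovered from another. OR of Q branches is the compensated index
(BIC-FADI); Q = 1 with the Wiener weights is the uncompensated
single-canceller variant.

An empty fused spectrogram has no occupancy distribution; the index is then
reported as an explicit *undefined* sentinel (`NA` with `defined = FALSE`),
never as 0 — zero is a legitimate value (all mass in one band) and
conflating the two would corrupt SINR sweeps.

## The scene simulator

The simulator emulates the simulation protocols: 60 s scenes, 30
band-limited 0.1 s noise-burst events (bands 1–12, 0.5–4 or 5–9 kHz) in
non-overlapping 2 s slots; a directional interference in the rear
half-plane; independent pink noise (1/f power, the standard model of
environmental fluctuation) on each channel. Propagation is far-field:
channel 2 receives each source delayed by ρ·cosθ samples via a 63-tap
Blackman-windowed-sinc fractional delay (interpolation error below −60 dB,
far beneath the 40 dB interference dynamics). Calibration is exact by
construction: the interference is scaled so that its channel-1 power over
the full scene sits at the target INR above the noise floor, and each event
is scaled individually over its own support so the average event-support
SINR equals the target; both are re-measurable to within 0.1 dB. Labels
record event supports (widened by the interpolator fringe) and the
complementary noise segments, so labelled samples contain zero event energy
by construction.

The aerator and drone recordings used as interference in the original
experiments are not distributable; the simulator substitutes synthetic
stand-ins with the features the algorithm actually assumes — directional,
broadband across the 1–12 kHz analysis band, quasi-stationary:

* `aerator_like` — stationary: shaped broadband noise spanning
  0.1–12.5 kHz with a gentle spectral tilt plus a fixed 100 Hz harmonic
  comb.
* `drone_like` — nonstationary: a harmonic comb whose ≈180 Hz fundamental
  wobbles slowly (±6 % at 0.15 Hz) with harmonics across the band, slow
  ±30 % amplitude modulation, over a broadband floor.

Within-slot event onsets are drawn once per seed (uniform in the slot with
a margin); the protocol fixes the schedule across a SINR sweep but does not
dictate a specific placement, so the placement is a per-seed choice and is
documented as such. Event band types are drawn with equal probability per
seed. Everything is bit-reproducible from the scene specification.

What passing tests on these scenes show — and what they do not: the scenes
exercise the geometry, the calibration, the subspace structure and the
threshold logic under controlled SINR/INR, but they contain no
reverberation, no moving sources, no multiple interferers, no
amplitude mismatch between microphones, and stand-in interference rather
than recorded machinery. Field behaviour (e.g. longer filters needed for
multiple aerators) is outside what the simulator can certify.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `delta` (δ) | 10 | forward-beam delay, samples; `h = 2δ+1` enforced |
| `h` | 21 | canceller taps (backward beam) |
| `fs` | 32 kHz | sample rate |
| `d`, `c` | 1.06 cm, 340 m/s | spacing and sound speed → ρ ≈ 0.998 |
| `frame_len` | 100 ms | STFT frame = hop (non-overlapping) |
| `fmax` | 12 kHz | analysis ceiling → K = 1200 bins of 10 Hz |
| `I`, `B` | 12, 1 kHz | sub-bands of the entropy index |
| `kL` | 20 | lowest bin for η₁ (200 Hz at 10 Hz bins) |
| `gamma1` (γ₁) | 20 | floating-threshold factor, linear power |
| `epsilon` (ε) | 1e5 | peak-to-η₁ ratio (50 dB) |
| `xi` (ξ) | 1e−7 | logarithm guard in the entropy |
| `zeta` (ζ) | 0.95 | retained energy fraction → subspace dim r |
| `Q` | 3 | fused branches (diminishing returns beyond 3) |
| `inr_db` | 40 | interference-to-noise ratio of rendered scenes |

γ₁ = 20 is interpreted as a linear power factor (≈13 dB), the reading
consistent with η₂(k) = γ₁·Qv(k); it is exposed in the configuration for
users who prefer a dB-calibrated value. kL = 20 corresponds to a 200 Hz
cutoff at the default bin width; it tracks the bin index, not a fixed
frequency, if the frame length is changed.

## Numerical choices

* **Covariance conditioning** — diagonal loading of 1e−10 × mean tap power
  is added before every inversion; near-singular systems are additionally
  reported. Long filters on strongly low-rank interference are otherwise
  ill-conditioned.
* **Eigenvector sign and ties** — each eigenvector's largest-magnitude
  element is made positive; equal eigenvalues keep the symmetric-eigen
  ordering. Branch weights are thereby reproducible bit-for-bit.
* **Transients** — beams are valid from the second sample; filtered outputs
  zero their first `h + δ` samples and mark `n0`. Statistics and
  spectrograms honour these markers.
* **Noise-level frames** — Qv uses only spectrogram frames lying *entirely*
  inside labelled noise segments, avoiding event contamination and
  concatenation artefacts.
* **Indexing** — formulas are 1-based in bin index k with physical
  frequency (k−1)·Δf; the sub-band rule is implemented on physical
  frequency to avoid off-by-one drift.
* **Degenerate inputs** — empty eigenvalue totals, insufficient sample
  support (Y < h+1), mismatched `h`/`δ`, events overlapping a slot, and
  missing noise labels are all hard errors; Y < 10h is a warning.

## Scope and problem sizes

The full study protocol — two interference stand-ins × 15 SINR points ×
seven index variants on 60 s, 32 kHz scenes with h = 21 and 22×22
eigendecompositions — is the problem size used by the acceptance script and
the heavier tests; unit tests use 6–12 s scenes with the same parameters.
The package deliberately excludes DOA estimation, automatic noise-segment
detection (labels are inputs), real-time/recursive adaptation, arrays with
more than two elements, and room acoustics.

The single Wiener canceller is exposed alongside the bank (`variant =
"wiener"`, reported as BIC-FADIw by the sweep drivers) so the
self-cancellation cost of the unconstrained design can always be compared
against the fused bank on the same recording.
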