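---
title: "Wavelet intermuscular coherence and antagonist co-contraction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet intermuscular coherence and antagonist co-contraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcoh)
```

## The scientific question

During a voluntary movement, synergistic muscles are not driven
independently: their motor-unit pools receive partially shared descending
input (the "common drive" idea). The frequency-resolved squared
correlation between two muscles' surface EMG signals — intermuscular
coherence (IMC) — is the standard proxy for that shared drive. In the
beta band (13–31 Hz), which carries the oscillations associated with
voluntary motor control, a higher IMC between two muscles is read as a
more common, less selective central command.

`imcoh` implements an analysis chain for a specific experimental design:
repeated discrete elbow extensions, with surface EMG of the long head of
the triceps brachii (TB, extensor/agonist), the biceps brachii (BB) and
the brachioradialis (BR, flexors and therefore antagonists of the
extension), elbow-angle kinematics on a slower clock, and separate
maximal-voluntary-contraction (MVC) trials on an isokinetic ergometer.
Two pairs are analyzed: BB–BR (antagonist–antagonist) and TB–BR
(agonist–antagonist). Alongside IMC the chain computes the antagonist
co-contraction index — how strongly the flexors are active *during
extension*, as a percentage of their MVC-referenced RMS — and a group
inference layer relating the two.

## The pipeline, stage by stage

### Preprocessing

Kinematics are low-pass filtered at 6 Hz; EMG is band-stop filtered at
49–51 Hz (power line) and band-pass filtered at 3–100 Hz. All filters
are fourth-order zero-lag Butterworth (forward–backward application, so
the effective order is doubled and the phase response is identically
zero). EMG is deliberately **not** rectified: coherence theory applies to
the raw interference signal, and rectification distorts both power and
coherence spectra.

Two numerical points deserve a note:

* Narrow notch filters in expanded polynomial `(b, a)` form are
  ill-conditioned; even with exact steady-state initial conditions a
  direct-form recursion drifts at the 1e-5 level. `zero_lag_butterworth()`
  therefore regroups the design polynomial into cascaded biquads
  (second-order sections) and initializes each section at its steady
  state, with odd-reflection end padding. A constant signal passes a
  49–51 Hz notch unchanged to ~1e-10.
* Angular velocity uses central differences (zero-lag, second-order
  accurate). Onset and offset of each movement are detected by a
  0.01 °/s threshold on the absolute velocity, searched *outward* from
  each velocity peak; excursions must exceed `min_peak_velocity` (5 °/s)
  to count as movements at all, which keeps the very low threshold
  usable in the presence of a noise floor. Because 0.01 °/s is tiny
  relative to one 8 ms kinematic sample, the crossing is refined by
  linear interpolation between the bracketing samples; on noiseless
  minimum-jerk movements the recovered bounds land within a few
  milliseconds of the analytic crossings.

Trials are segmented with 3 s pads on each side (`extract_trials()`).
The pads exist so that wavelet edge effects fall outside the movement;
they are cropped again after the transform. Kinematic event times are
mapped to the EMG clock by nearest-sample conversion — signals themselves
are never resampled, since resampling would distort the EMG spectrum.

### Time–frequency coherence

The Morlet continuous wavelet transform is evaluated on a **linear**
grid of `nvoice * J1 = 350` frequencies with spacing 79.97/350 ≈
0.2285 Hz, i.e. spanning ≈0.23–79.97 Hz in 0.23 Hz steps, with Morlet
wavenumber (ω₀) 10. This grid reproduces all three printed grid
constants of the protocol the package targets; with ω₀ = 10 it yields
roughly a 0.1 s × 3 Hz resolution cell in the beta band. The transform
is computed in the frequency domain (one FFT of the zero-padded signal,
multiplication by the analytic Morlet spectrum per frequency, one
batched inverse FFT), which is mathematically the same linear
convolution a direct time-domain implementation computes — the test
suite checks agreement with an independent direct-convolution oracle at
1e-6.

Auto- and cross-spectra are averaged across the K movements of a
session after cropping the pads and aligning trials at their
peak-velocity time (the anchor of the quantification window):

> R²(ω,u) = |S₁₂(ω,u)|² / (S₁(ω,u) · S₂(ω,u))

with S₁₂ the trial-averaged cross-spectrum and S₁, S₂ the trial-averaged
auto-spectra. Averaging over K ≥ 2 trials is essential: the single-trial
ratio is identically 1. Under independence the K-trial estimate has
expectation ≈ 1/K, and exceeds

> threshold = 1 − α^(1/(K−1))

with probability α (0.1459 for K = 20, α = 0.05) — this analytic rule is
the default significance mask. The original protocol delegates its
significance contours to an external toolbox whose exact procedure is
not described; the analytic rule is a stated substitute, and a surrogate
alternative (threshold from trial-shuffled pairings, which destroys
within-trial coupling but keeps every marginal spectrum) is available
via `significance = "surrogate"`. The rule used is recorded in the
result object.

IMC is quantified as the **volume under significant coherence** in the
beta band and the 200 ms before peak velocity:
`volume = Σ msc·mask · Δf · Δt` (units: coherence · Hz · s). Two
conventions were genuinely open and are resolved as follows: raw MSC is
summed over significant cells (not MSC − threshold; the alternative is
available behind `subtract_threshold`), and the time-normalization step
used elsewhere for display purposes is applied only to the *display*
axis of full-movement maps (`autoplot(..., percent_time = TRUE)`), never
to the raw signals — the 200 ms window is defined in absolute time, and
resampling EMG would distort its spectrum. The same window also yields
the mean elbow angle and mean angular velocity used later as model
covariates.

### Antagonist co-contraction

For each movement, each flexor's RMS over `[onset, offset]` is divided
by that muscle's MVC reference RMS; per-movement values average the two
flexors, and the session index averages movements (× 100%). The
per-muscle-ratio-first order makes the index invariant to per-channel
amplifier gains, which the alternative reading of the ambiguous
"average RMS / average MVC RMS" is not. The MVC reference is computed on
the central 3 s plateau of the 5 s contraction whose plateau torque is
maximal among the three trials. MVC EMG passes the same filters as
movement EMG so that the ratio is not biased by passband shrinkage.
Whether the co-contraction window should instead be the 200 ms IMC
window is not specified by the protocol; `[onset, offset]` is
implemented ("during elbow extension").

### Group statistics

* `two_sample_t()`: pooled-variance t (df = n₁+n₂−2), Cohen's d with a
  normal-approximation (Hedges) 95% CI — the CI method of the original
  report is unstated, so the method used is recorded in the object.
* `boxcox_transform()`: profile-ML λ. Coherence volumes can be exactly 0
  (no significant cells); since the transform needs positivity and the
  protocol is silent, half the smallest positive value is added as an
  offset when zeros are present, and both λ and the offset are recorded.
* `ancova_imc()`: for one limb contrast, a linear model of the
  transformed volume on limb, muscle pair, their interaction and four
  covariates (window angle, window velocity, age, co-contraction), with
  sum-to-zero factor coding and type-III sums of squares, partial η² =
  SS/(SS+SS_error), and a corrected α = 0.017 significance flag. The
  three limb contrasts are fitted as three separate 2×2 models, not one
  three-limb model, and an unbalanced limb × pair design is an error
  naming the offending cells.
* `partial_spearman()`: rank everything, regress both target rank
  vectors on covariate ranks, correlate the residuals; p from a t
  reference with n−2−k df, CI by Fisher z. The outlier rule — drop
  points beyond two residual SEs — is applied to *either* regression's
  residuals (the protocol does not say which; "either" is the
  conservative reading), and the analysis is always reported both with
  and without the flagged points, re-ranked on the retained subset.

The pooled t with df = n₁+n₂−2 gives t(46) for 24 vs 24 subjects; the
cohort report prints t(47) for one of its tests, an inconsistency this
package does not reproduce.

## The synthetic-data generator

No public recording of the clinical dataset exists, so the generator is
a first-class module that emulates exactly the statistical structure the
analysis assumes, with ground truth attached:

* **Kinematics**: minimum-jerk extensions (θ(t) = θ₀ + Δθ(10τ³−15τ⁴+6τ⁵)),
  by default 90°→160° in 1 s, each followed after a randomized 8–15 s
  rest by a slower return flexion (detected and excluded by the
  positive-direction filter, mirroring a protocol where only extensions
  are analyzed); 20 extensions per session at 125 Hz, EMG at 1000 Hz.
* **EMG**: channel i is `aᵢ·s + nᵢ`, where `s` is the common drive —
  white Gaussian noise shaped by the same zero-lag 13–31 Hz band-pass
  the preprocessing uses, rescaled to an exact in-band PSD — and `nᵢ` is
  independent 3–100 Hz noise. Powers are **spectral density levels**
  (V²/Hz): that convention is what makes the closed form
  `(a₁a₂Pₛ)²/((a₁²Pₛ+P₁)(a₂²Pₛ+P₂))` describe the in-band coherence
  (equal source and noise density ⇒ 0.25); with total-variance
  semantics the in-band SNR would be inflated by the ratio of the
  Nyquist range to the drive bandwidth (≈28×) and the closed form would
  not hold. Muscle noise is band-limited to the EMG band rather than
  white so that the downstream 3–100 Hz filter affects movement and MVC
  recordings identically.
* **Planted co-contraction**: during each extension (plus a 0.3 s margin
  so that detected bounds, smoothed by the 6 Hz filter, stay inside the
  scaled region) the flexor samples are rescaled so the RMS over the
  movement equals `cocontraction_ratio × mvc_rms` exactly. Constant
  per-window scaling leaves coherence untouched. TB gets a constant
  agonist burst gain for realism.
* **MVC**: three 5 s trials with trapezoidal torque (1 s ramps, 3 s
  plateau); one designated trial gets +10% torque, exercising the
  maximal-torque selection rule; flexor plateau RMS is planted exactly.
* **Determinism**: one seed controls all noise; a separate timeline
  stream draws rest durations and the maximal-MVC trial, so different
  noise seeds share identical event times.
* Movement-to-movement amplitude variability is not constrained by the
  protocol, so it is exposed (`movement_amplitude_cv`, default 0) rather
  than asserted; likewise kinematic sensor noise (`angle_noise_sd`,
  default 0, i.e. noiseless optical capture).

What the generator does **not** emulate: motor-unit physiology,
nonstationary spectra within a movement, crosstalk between electrodes,
amplitude-dependent noise, or lesion anatomy. Tests passing on this
generator therefore establish that the *estimators* are correct under
the model the analysis itself assumes — not that the clinical
conclusions replicate on real data, which are not available.

## Problem sizes and numerical choices

The verification suite balances fidelity against desk-scale runtimes;
the sizes are the package's own choices:

* Null-calibration and identity checks run K = 20 trials at a reduced
  250 Hz rate — the analytic threshold and the 1/K bias are
  rate-independent — with segments longer than one period of the lowest
  (0.23 Hz) grid frequency.
* Planted-coherence recovery averages 10 seeds of K = 20 trials at
  1000 Hz, restricted to the beta band (the per-frequency estimates are
  independent of whether other frequencies are computed, so restricting
  the grid is purely a cost choice; `build_frequency_grid(range =)`
  keeps Δf fixed so volumes are unchanged).
* The in-band comparison against the 0.25 closed form evaluates
  15–29 Hz, clear of the band edges where the shaping filter's
  forward–backward response (|H|⁴) rolls off and the true coherence
  dips below its mid-band value.
* Volume-vs-coupling monotonicity averages a fixed set of 8 seeds per
  gain: at the weakest coupling (0.3) the true in-band coherence
  (0.0068) sits far below the K = 20 detection threshold, so a single
  realization is dominated by the false-positive mass and can order
  arbitrarily; the seed-averaged volumes restore the expected ordering.
* ANCOVA type-I calibration uses 2000 null replicates at 24 subjects
  per group; the end-to-end two-group check uses 10 subjects per group
  with the coherence grid restricted to 11–33 Hz.
* Degenerate inputs: zero auto-spectrum cells become NA with a warning
  rather than Inf; coherence is clipped to [0, 1] against rounding;
  movements whose pads leave the recording are dropped with a warning;
  an all-zero-torque MVC set, a missing flexor channel, and an
  unbalanced ANCOVA design are errors.

## Known limitations

* The significance rule is a principled substitute, not the (unpublished)
  original procedure; both available rules are recorded in the output.
* The analytic threshold treats cells independently; no cluster-based
  correction across the time–frequency plane is attempted (out of
  scope).
* Coherence near segment edges within one cone-of-influence width is
  attenuated; the 3 s pads push this outside the movement, but very
  low frequencies (< ~1 Hz) remain edge-dominated on single movements —
  irrelevant for the beta band.
* The co-contraction index assumes the MVC reference is a valid
  amplitude yardstick for the movement electrodes (same placement, same
  session); the generator plants this by construction.
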