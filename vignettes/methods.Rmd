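---
title: "Models and methods behind gridtheta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gridtheta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gridtheta` analyzes open-field MEC recordings collected under
alternating light and dark epochs: spatial firing structure (grid,
border, head-direction coding), theta-rhythmic spiking, the coupling of
LFP theta frequency to running speed, and how all of these change when
visual input is removed. This vignette explains the models, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was open.

## The session model

A session is a list of tables: tracking at 50 Hz (`t, x, y, hd`; lost
samples stored as `NA`, never interpolated — fabricating positions would
bias occupancy maps and the Kalman speed), per-unit spike times with
waveform widths, an optional 600 Hz LFP trace, and an epoch table of
half-open `[start, end)` intervals whose conditions alternate. A spike
at exactly an epoch's end time belongs to the next epoch, so condition
views partition session time exactly. `slice_by_condition()` restricts
tracking and spikes to one condition's epochs and carries those epochs
as provenance; the raw LFP is deliberately kept whole, because
band-pass filtering concatenated segments would distort phase at the
seams — theta measures are masked on the aligned 50 Hz grid instead,
with the first and last 0.5 s of every epoch excluded from frequency
statistics to suppress Hilbert edge artifacts and transition smear.

## Derived signals

Running speed comes from a 2D constant-velocity Kalman filter (state
`[x, y, vx, vy]`), white-acceleration process noise `q = 10 (cm/s²)²/s`
and measurement noise SD 0.5 cm by default. With these defaults a
stationary target jittered by 0.5 cm of tracking noise reads out below
1 cm/s, while true constant motion is tracked within 2%. The two axes
decouple, so the filter runs as two scalar position–velocity filters
with the steady-state gain; acceleration is the centered difference of
the speed magnitude, smoothed with the same 125 ms Gaussian used for
firing rates. Instantaneous firing rate is spikes per 20 ms frame
divided by the frame period; before smoothing its integral equals the
spike count exactly.

The theta band is located as the largest spectral peak in 4–12 Hz of a
smoothed periodogram, ±2 Hz (clipped to [4, 12]); if no peak exceeds
1.5× the broadband background the fixed 6–10 Hz band is used with a
warning. The band-passed signal (zero-phase third-order Butterworth, so
phase estimates are unbiased) is converted to an analytic signal by the
FFT construction, giving phase, amplitude, and frequency (unwrapped
phase derivative, clipped to 0.5–20 Hz).

## Spatial maps and scores

Rate maps divide the arena into bins of nominally 3 cm; the effective
bin side is `arena_side / round(arena_side / 3)` so the grid partitions
the arena exactly — an overhanging grid would break the reflection
symmetries that the border score and the arena-symmetry invariants rely
on. Smoothing is applied to the rate surface with the kernel
renormalized over visited bins only.

The grid score follows the rotation-spectrum construction: (1) find the
six autocorrelogram peaks closest to the center, (2) fit an ellipse
through them and affinely map it to a circle (eccentricity correction),
(3) correlate an annulus enclosing the peaks (inner radius 0.5× the
minimum peak distance, outer 1.25× the maximum) with itself rotated in
3° steps, (4) report the power of the 6-cycles-per-rotation component
of that curve divided by the total power of components 1–10.

Two validation gates precede scoring, and they matter. Peaks are
detected as connected autocorrelogram fields above 0.1 with at least 6
bins, and the six selected peaks must actually be arranged as a
(possibly elliptical) hexagon: peak distances within a factor 1.3 and,
after eccentricity correction, adjacent peak angles within ±15° of 60°.
Without these gates the score's null distribution is badly behaved for
two structural reasons: rotation-correlation curves of point-symmetric
autocorrelograms are 180°-periodic (odd spectral components are
identically zero, halving the effective denominator), and forcing six
arbitrary noise blobs onto a circle via the ellipse correction
manufactures pseudo-hexagons in roughly a fifth of smoothed-noise maps.
With the gates, noise maps pass to scoring at the few-percent level and
true synthetic grids (which show distance ratios ≤ 1.11 and angular
deviations ≤ 4°) always pass.

Spatial information is the delta entropy `ΔH = log2(n) − H(X|spike)`
over the `n` visited bins, with `0·log 0 := 0`. The spike-triggered map
accumulates occupancy and spikes over the 10 s after every spike in
coordinates relative to the bin at the spike; its radial profile
(circle-circumference averages at 1-bin ring thickness) peaks first at
the grid spacing. Because circle *averaging* carries a `1/r` factor,
the first peak sits below the true spacing by about
`σ_eff²/spacing`, where `σ_eff²` combines twice the field variance with
the 3 cm map smoothing — about 2 cm at 42 cm spacing with realistic
field widths. This bias is a property of the radial-average estimator
itself and is left uncorrected; the profile is lightly smoothed (SD
2 cm) and the peak is read as the top of the first prominent hill with
parabolic sub-grid refinement, which removes noise wiggles without
touching the estimator's definition.

The border score is `(cM − dm)/(cM + dm)` with fields defined as
connected components above 0.3× the peak rate covering at least
200 cm². Head-direction tuning uses 60 six-degree bins; the MRL and
preferred direction come from the rate-weighted resultant of bin
centers, the circular SD is `sqrt(−2 log MRL)`, and the Rayleigh test
is applied to spike head directions.

## Theta rhythmicity

Spike-time lags (all ordered pairs within 0.6 s and the same contiguous
analysis segment) are modeled with the normalized density

`g(t) ∝ [(1 − a)e^(−t/τ) + a]·[1 + r·e^(−t/υ)·cos(2πft)]`

with `a ∈ [0,1]`, decays `τ, υ ∈ [0.01, 10]` s optimized in log10
space, magnitude `r ∈ [0,1]`, and frequency `f ∈ [1,13]` Hz. The
likelihood is evaluated on a 0.25 ms Simpson quadrature grid (the
normalization error is below 1e-9) with lags binned to the same grid,
which makes each evaluation a single vector operation. Optimization is
multi-start: a 4-parameter profile fit at each 0.5 Hz frequency
between 1 and 13, then full 5-parameter refinement from the three best
starts. Fits are refused below 100 lags, where the model is
unreliable. Significance is a likelihood-ratio test against the
`r = 0` null on 3 df (`r, υ, f`); this choice is conservative in
principle (the magnitude sits on a boundary under the null) but the
maximization over the frequency grid works in the opposite direction,
and the test's measured type-I rate at α = 0.1 over seeded homogeneous
Poisson trains is close to nominal — the calibration simulation is part
of the test suite.

Note one property of sinusoidally rate-modulated Poisson trains used in
the tests: modulation depth `d` in the rate appears as `d²/2` in the
lag density, so recovered magnitudes are expected to be smaller than
the programmed rate-modulation depth while remaining strictly monotone
in it.

Speed-resolved fits pool lags from stable-speed epochs (speed within
±4 cm/s over at least 400 ms) into 1 cm/s bins spanning 1–29 cm/s;
time-resolved fits pool 10 s offset windows across all epochs of a
condition, and the population frequency is read from the inverse of
the first local maximum (beyond 50 ms, 1 ms grid) of the across-unit
mean of the fitted model curves. Phase locking interpolates the
unwrapped theta phase at spike times, restricted to running above
5 cm/s and at least 30 spikes, and summarizes the phase-binned
(36 × 10°) occupancy-normalized rates by their rate-weighted MRL.

## LN Poisson tuning model

The conjunctive tuning model is Poisson with log link, additive in
one-hot binned covariates: position (10×10 over the arena), head
direction (18 bins), theta phase (18), and speed (15 bins over
0–30 cm/s, clipped). A quadratic roughness penalty (weight 5, circular
adjacency for the angular covariates) regularizes the weights; fitting
is L-BFGS with analytic gradients computed by per-bin residual sums, so
a fold fit on a 10-min session takes well under a second. Forward
selection starts from the best single covariate by 10-fold blocked
cross-validated log-likelihood gain over the mean-rate model and adds
covariates while a one-sided signed-rank test across folds is
significant at 0.05; a unit whose best model never beats the mean-rate
model is labeled unmodulated, a valid outcome.

Speed response curves are the exponentiated speed weights scaled to the
model's mean rate, reported only over speed bins with at least 10 s of
occupancy (sparser bins are dominated by Poisson noise). `within`
normalization divides each condition's curve by its own maximum;
`across` divides both conditions by the light-condition maximum, which
is what preserves condition-wide gain changes. Speed cells are split
into positive and negative groups by Ward clustering of
quadratic-polynomial fits to their within-normalized curves.

## Light/dark contrasts

Epoch modulation computes per-epoch mean rates and applies a paired
t-test to the *disjoint* (light, following dark) pairs. The overlapping
pairing in which every epoch enters two differences makes adjacent
differences positively correlated and inflates the nominal level about
threefold; with disjoint pairs the measured false-positive rate on null
units matches α. Units must show activity across at least three
light-to-dark and three dark-to-light pairs to be included, and a unit
with exactly constant nonzero differences is reported modulated with
certainty rather than discarded for zero variance.

The speed-adjusted dark/light ratio integrates each condition's speed
tuning curve against the *light* condition's speed-occupancy
distribution, isolating tuning change from the slight behavioral
slowing in darkness. Theta-frequency (or amplitude) vs speed
regressions are ordinary least squares over samples with speed in
[2, 30] cm/s — the lower cutoff removes immobility, where theta
estimates are unreliable. Time courses pool 50 Hz samples across all
epochs of a condition by 10 s offset bin and apply a metric extractor
per bin (regression slope/intercept, pooled-map grid score or spatial
correlation, mean frequency, ...); saturating-exponential summaries
`a + b(1 − e^(−t/τ))` are fitted by least squares and reported
descriptively.

## The synthetic-session generator

The generator emulates the study design: a 1 m arena, 42-min sessions
of 3-min alternating epochs starting with light, and foraging at
11.6 cm/s mean speed. The trajectory model is a truncated
Ornstein–Uhlenbeck speed process (SD 5 cm/s, time constant 2 s — slow
enough that the Kalman estimate tracks the true speed closely, which is
what makes closed-loop slope-recovery meaningful), a smoothly varying
angular velocity (OU, SD 2 rad/s, time constant 0.5 s), and reflection
at the walls. Head direction is the movement heading plus small von
Mises jitter. Forty-minute trajectories visit over 95% of 3 cm bins.

Tuning functions are composable: hexagonal-lattice Gaussian fields
(default field SD = spacing/7, a standard field-to-spacing ratio;
wider fields inflate the radial-profile spacing bias beyond the
method's bin resolution), wall-strip border fields, von Mises
head-direction tuning, linear / saturating / bell-shaped speed tuning,
and sinusoidal theta-phase modulation riding on the simulated LFP
phase. Conjunctive cells multiply mean-normalized gain factors, which
corresponds to additivity in log rate and makes LN-model recovery
well-posed. Spikes are drawn by Poisson thinning at 1 ms resolution.
The LFP is a unit-amplitude cosine whose instantaneous frequency is
linear in running speed with condition-specific slope and intercept
(defaults 0.05 and 0.02 Hz/(cm/s) at 7.2 Hz), integrated continuously
across epoch boundaries, plus white noise; an optional within-epoch
slope ramp (saturating exponential, default time constant 40 s)
emulates the slow post-transition drift of the speed slope.

What the generator does *not* emulate: spike sorting artifacts,
non-Poisson spike-history structure (refractoriness, bursting), theta
cycle skipping, broadband or non-theta LFP structure, slow
representational drift, and behavioral coupling between condition and
running statistics (the slight slowing in darkness is configurable but
off by default). Passing the recovery tests therefore demonstrates that
the estimators are correct on data satisfying their assumptions, not
that real recordings satisfy those assumptions.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make the
statistical checks decisive while keeping a laptop run comfortable:
20-min sessions for the grid pipeline (10 seeds per spacing, 100 noise
maps), 10-min trains for rhythmicity calibration (100 null seeds, 50
recovery fits), 21-min sessions for the condition-slope recovery,
10–15-min sessions for LN selection (30 fits), a 60-min session for the
normalization check, and 100 + 100 seeded units for epoch-modulation
calibration. The full suite runs in about seven minutes on one CPU.

## Known limitations

The spike-triggered spacing estimator inherits the inward bias of
circle-averaged radial profiles (~2 cm at 42 cm spacing); for spacings
approaching the arena size (60 cm in a 1 m box) few field pairs exist
at the ring distance and the estimate scatters by ±5 cm across seeds.
The grid-score scale saturates near 1 for clean synthetic grids, so the
0.19 classification threshold should be recalibrated before applying
it to scores produced by other normalizations. The LRT reference
distribution for rhythmicity is asymptotic and boundary-affected; its
calibration is verified empirically rather than assumed. LN fits use
fixed bin counts and penalty weights; strongly non-stationary sessions
would need the blocked cross-validation folds rethought.
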