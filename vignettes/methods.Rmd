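---
title: "Models and methods behind synaptoglu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptoglu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoglu)
```

# What the package models

`synaptoglu` analyses two readouts of glutamate release at large calyceal
synapses such as the endbulb of Held: postsynaptic currents recorded by
whole-cell patch clamp (sampled at 40 kHz) and fluorescence of a
membrane-anchored glutamate reporter (iGluSnFR-type, imaged at a 100 Hz
frame rate). Both observe the same presynaptic event sequence through
different linear-ish transformations, and the package's central question is
how well the optical readout reproduces the quantitative measures that
electrophysiology provides: quantal event statistics, paired-pulse ratios,
and vesicle-pool parameters from cumulative train analysis.

Three models do the work.

**Vesicle pool.** A readily releasable pool (RRP) of `n_rrp` vesicles
releases a Binomial(`N_i`, `p_r`) quantum count on each stimulus and
refills between stimuli at `refill_rate` vesicles/s, clipped at capacity.
The deterministic mode replaces draws by expectations, giving the exact
geometric depletion sequence `released_i = n_rrp * p_r * (1 - p_r)^(i-1)`
(refill-free case) that serves as a closed-form oracle throughout the
tests.

**Quantal currents.** Each released vesicle contributes an instant-rise,
single-exponential inward current (amplitude ~127 pA, decay ~0.145 ms;
evoked responses use ~0.33 ms, the slower decay of compound EPSCs).
Evoked responses follow the stimulus with a ~0.9 ms synaptic delay.

**Reporter kinetics.** A released vesicle elevates delta-F/F by `s0`
instantaneously; bound reporter decays monoexponentially with time
constant `tau` (38.43 ms at 2 mM external calcium, 68.66 ms at 4 mM).
The continuous fluorescence signal is the convolution
`s(t) = s0 * integral x(t') exp(-(t - t')/tau) dt'` of the release-rate
train `x(t)` with that kernel. Inverting this convolution — estimating
`s0 * x(t)` from `s(t)` — is the methodological core, and two estimators
are provided (below).

# The synthetic-data generator

Every stage of the pipeline is testable without recorded data because the
generator produces ground-truthed traces under the study conditions:
40 kHz current sampling with ~5 pA RMS noise; spontaneous quantal events
as a Poisson process at 7 Hz with log-normal amplitudes (CV 0.3) around
127 pA; 100 Hz fluorescence frames with Gaussian count noise over a
baseline of 1000 counts; and, in image mode, a cup-shaped ROI (a 240
degree annular arc, inner radius 8 px, width 4 px — fixed, arbitrary
geometry standing in for the calyx seen edge-on) painted over a dimmer
background.

Choices worth knowing about:

* **Frames are exposure-averaged, not point-sampled.** With a ~38 ms decay
  and 10 ms frames the within-frame integration bias is a real feature of
  camera data and is modeled in closed form (the average of an exponential
  over the exposure window).
* **Optical release impulses sit at the stimulus time.** The ~0.9 ms
  synaptic delay matters at the 40 kHz current grid and is included there,
  but is negligible on the 10 ms frame grid; placing optical events at the
  stimulus keeps release impulses aligned with frame boundaries for
  protocols on the frame grid.
* **Mini onsets snap to the sample grid.** An instant rise starting
  mid-sample renders a peak attenuated by `exp(-u * dt / tau)` with `u`
  uniform, i.e. about 8% on average at these scales — an artefact of
  placing idealised discontinuous events on a grid, not a property of real
  synapses. Snapping makes the generator's nominal amplitude the actual
  peak in the trace.
* **`s0` defaults to 0.025 per vesicle** so that a typical first evoked
  response of ~12 quanta gives an instantaneous peak delta-F/F of 0.30,
  the scale observed at this synapse. The 100 Hz frame-averaged observable
  peaks somewhat lower (~0.26) — that distinction is inherent to slow
  frames and worth remembering when comparing numbers.

What the generator does **not** emulate: diffusion and buffering of cleft
glutamate, receptor desensitisation or saturation (unless injected
deliberately), photobleaching, lateral motion, correlated camera noise,
multi-synapse contamination of the ROI, and the heavy-tailed variability
of real cells. Passing tests therefore demonstrate the *estimators'*
correctness on data satisfying their assumptions, not robustness to every
pathology of real recordings.

# Signal primitives

Corner frequencies define filters by their -3 dB amplitude point. For the
Gaussian filter this fixes the time-domain width
`sigma_t = sqrt(ln 2) / (2 pi f_c)`; for the binomial filter the pass
count of the (1, 2, 1)/4 kernel is
`n = max(1, round(ln 2^(-1/2) / (2 ln cos(pi f_c dt))))` — one pass for an
8 kHz corner at 40 kHz sampling. Both use reflective edge handling and
preserve trace length.

Exponential decay fits use log-linear initialisation followed by
Levenberg-Marquardt least squares (tolerance 1e-8, 200 iterations) on a
rescaled problem: amperes (~1e-10) against seconds (~1e-4) make the raw
gradient matrix numerically singular, so fitting happens in units of the
initial amplitude and time constant. Non-convergence is flagged, never a
silent NaN.

Baseline noise uses 1.4826 x the median absolute deviation of the
detrended window rather than the raw RMS, because detection windows
contain events; the plain RMS is available (`method = "rms"`) and is used
where the window is event-free by construction (SNR baselines).

FWHM interpolates threshold crossings linearly, except that an entry whose
preceding sample is far below the half level (< 1/5 of it) is treated as
an unresolved instantaneous rise — this is what makes the FWHM of an
ideal instant-rise exponential come out at `tau ln 2` to within half a
sample instead of being systematically half a sample long. Event charge
integrates to return-to-baseline with a 5-tau cap.

# Miniature event detection

The detection pipeline smooths at 8 kHz (binomial), then requires
coincidence of two 5-sigma criteria within +/-0.5 ms: a deviation in the
further 2 kHz Gaussian-filtered trace and a deflection in the 4 kHz
Gaussian-filtered derivative (central differences of the smoothed trace).
Candidates closer than 1 ms merge, keeping the larger. The coincidence
window and merge distance are much smaller than the mean inter-event
interval at 7 Hz and much larger than the event rise time, which is the
range in which their exact values do not matter.

Manual inspection of candidates is replaced by explicit programmatic
rules — a converged decay fit with positive time constant, a rising phase
that slopes toward the peak, a width of at least two samples — a
deliberate deviation from interactive practice that reproducibility
requires. Kinetic fits run on the smoothed trace; amplitude, charge and
width are measured on the raw trace, because one pass of the binomial
kernel attenuates a 0.145 ms event peak by ~15%, and the measurement
window opens 0.25 ms before the estimated onset so an onset estimate one
sample late cannot clip the amplitude.

# Train metrics and pool analysis

Per-stimulus amplitudes are measured against a 1 ms pre-stimulus local
baseline, with the fitted exponential continuation of the previous
response subtracted (irrelevant at 10 ms ISI for 0.33 ms currents,
essential for fluorescence analogues). The cumulative-amplitude (SMN
style) analysis fits an ordinary least-squares line through the last 10 of
25 cumulative points and evaluates it at stimulus index 0 — the ordinate,
not index 1. The intercept estimates the pool in response units, the slope
per ISI (reported per ms) the replenishment, and the first response over
the intercept the *uncorrected* apparent release probability
`y1/y_intercept`; no depletion correction is applied, so optical and
electrical estimates remain directly comparable and share one estimator
(`y1_over_intercept()`), which accepts any per-stimulus response sequence.

Two honest caveats, both verified in the test suite: with `fit_last_k =
10` the geometric approach to steady state leaves a residual that keeps
`|p_apparent - p_r|` below 0.005 only for `p_r >= 0.3` at 25 stimuli
(weaker depression needs longer trains — the error at `p_r = 0.2` is
0.014 at 25 stimuli and falls below 0.005 by ~40); and the estimator is
scale-invariant but flags non-depressing (affine cumulative) sequences as
unreliable rather than returning a zero-division artefact.

# Deconvolution

**Wiener.** The reporter kernel is sampled on the trace grid as a
unit-integral instant-rise exponential — the unit integral is what gives
the output release-rate units. The trace is zero-padded to at least twice
its length (next power of two), and the estimate is
`X(f) = S(f) H*(f) / (|H(f)|^2 + 1/SNR)` with a constant (scalar SNR)
regularizer, matching the per-recording SNR definition: the squared
quotient of maximum response amplitude and baseline RMS noise. Zero noise
degrades gracefully to the inverse filter (`snr = Inf` sentinel).

**Linear kernel.** Differentiating the convolution model gives
`s0 x(t) = ds/dt + s(t)/tau`, computed with the forward difference
`(s(t+dt) - s(t))/dt`. One numerical decision matters here: the forward
difference is naturally centered at `t + dt/2`, so the `s/tau` term is
evaluated there too (two-sample average). With the left-sample evaluation
the operator has an O(dt/tau) bias that leaves ~12% residual release rate
on pure decays at 10 ms frames and 38 ms tau; the midpoint evaluation
reduces the bias to O((dt/tau)^2) and the noiseless {12, 6, 4, 3}
round-trip error from ~2% to ~0.1%. The left-sample form remains available
(`s_eval = "sample"`). The final sample has no forward difference; it
copies its predecessor and is flagged.

Per-sample uncertainty uses first-order Gaussian quadrature,
`sigma_r^2 = 2 sigma_s^2/dt^2 + sigma_s^2/tau^2 + (s/tau^2)^2 sigma_tau^2`.
A linear-combination variant of this formula circulates in print with
inconsistent signs for a variance propagation; it is provided verbatim
behind `error_form = "printed"` for comparison but is not the default, and
no intent is assumed behind its signs.

Per-stimulus release windows on the deconvolved trace start **one frame
before** each stimulus: when release falls inside a frame, the forward
difference at the preceding frame already carries part of it, and naive
stimulus-aligned windows would leak release backwards. Release per window
is the peak by default (the convention for reading deconvolved responses),
with the integral as an option; integrals are what the round-trip tests
check, since they are exactly conserved.

`estimate_tau()` fits the post-train decay and is an upper bound for the
true reporter constant whenever release has not fully stopped at the
window start; the result carries that flag.

# Imaging

The delta-F image is the pixelwise mean over response frames minus the
mean over baseline frames (default response window: frames 1-10 after the
first stimulus of a 100 Hz train, covering the rising ~100 ms).
Segmentation realises "histogram-based" as Otsu's criterion on the
sigma = 3 Gaussian-blurred image (percentile thresholding is the
switchable alternative), keeps the connected component containing the seed
point — the "semi-automatic" element — or the largest without one, and
fills holes. The liberal blur makes the mask an outer bound of the true
terminal, which is the intended reading; accuracy is therefore assessed
against the truth mask dilated by the blur radius. delta-F/F divides by
the plain pre-stimulus baseline mean; no autofluorescence subtraction
beyond that is attempted.

Per-pulse AUC integrates delta-F/F over each inter-stimulus window after
subtracting the exponential continuation of the preceding signal — for
frame-averaged data that continuation is exactly the last pre-window frame
value decayed by `exp(-k dt/tau)`, so the overlap correction is closed
form. Sub-2-frame ISIs are rejected toward the deconvolution path.

# Optical vs electrical comparison and statistics

The calibration regression is constrained through the origin
(`slope = sum(xy)/sum(x^2)`), with R^2 computed about the mean of `y`
(which can legitimately be negative for the constrained model; negative
values are reported as-is and flagged), a t-test on the slope with n - 1
degrees of freedom, and the mean squared distance to the identity line
`d` as the agreement summary.

One subtlety the package documents rather than hides: for a depressing
train normalized to its first (largest) response, a *saturating* optical
transform is concave, which **inflates** later normalized responses — the
regression slope rises above 1. The slope falls below 1, matching the
intuition "saturation compresses the optical readout", only when both
readouts are compared in absolute units calibrated in the linear regime
(e.g. quantal units). Both behaviours are tested; both detect the
nonlinearity, with `d > 0`.

Rank-sum testing delegates to the standard implementation with a fixed
policy — exact enumeration when the combined sample size is at most 12
without ties, normal approximation with tie correction otherwise — and is
verified against brute-force enumeration of all C(m+n, m) rank
assignments. Two-sided tests throughout. The random-cell-intercept mixed
model is fitted by profiled maximum likelihood in-package (the variance
ratio is optimised on a log scale with an explicit boundary check at zero
cell variance), with a Wald p-value; on balanced data with no cell
variance it collapses to the difference of condition means, and its
estimates agree with an established mixed-model implementation to well
within three significant figures, which is the contract an independent
cross-check enforces in the test suite. Error propagation is first-order
Gaussian with independent inputs and analytic gradients.

# Problem sizes and reproducibility

The test suite and the acceptance script use the study-condition scales
directly: 60 s of 40 kHz miniature recording (~420 events at 7 Hz), 25
stimuli at 100 Hz for pool analysis (20 stochastic trains for the
recovery study), 10-stimulus 10 Hz trains for the optical/electrical
comparison, 64 x 64 x ~70-frame image stacks, 50 null simulations for the
mixed-model size check, and 1e5 Monte-Carlo draws for the error
propagation cross-check. All randomness flows from explicit seeds; a
fixed configuration and seed reproduce every generated dataset
byte-identically.

# Known limitations

* The reporter model is strictly linear and monoexponential; real
  indicators saturate, and their decay depends on the amount of released
  glutamate. Saturation can be injected for sensitivity analyses but is
  not part of the default model.
* Pool analysis inherits all caveats of back-extrapolation with few
  stimuli and incomplete depletion; `y1/y_intercept` is deliberately
  uncorrected and should be read as an *apparent* release probability.
* The detector's acceptance rules approximate, but are not, expert visual
  inspection; they are tuned for the clean statistical structure the
  generator produces.
* Deconvolution on the 100 Hz frame grid cannot resolve release structure
  within a frame; at 100 Hz stimulation each inter-stimulus window is a
  single frame and only integral quantities are meaningful.
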