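# synaptoglu

Quantitative comparison of optical and electrophysiological readouts of
synaptic glutamate release at fast calyceal synapses (endbulb of Held
type), with a ground-truthed forward simulator that makes every analysis
stage testable without recorded data.

Fluorescent glutamate reporters (iGluSnFR and relatives) promise direct
optical access to presynaptic release, but their slow decay (tens of ms)
and frame-rate-limited sampling (100 Hz) blur the millisecond structure
that patch-clamp recordings resolve. `synaptoglu` implements the analysis
machinery needed to put both readouts on the same footing:

* **Signal primitives** — corner-frequency-defined Gaussian and binomial
  filters, single-exponential and affine kinetic fits, robust (MAD-based)
  noise estimation, amplitude/charge/FWHM event measures.
* **Miniature EPSC analysis** — dual 5-sigma detection on filtered trace
  and filtered derivative, programmatic acceptance rules, per-event
  kinetics, per-cell medians and peak-aligned average waveforms.
* **Evoked trains** — per-stimulus amplitudes with tail-overlap
  correction, paired-pulse ratios, and cumulative (SMN-style) pool
  analysis: a line through the last-k cumulative responses,
  back-extrapolated to the ordinate, giving RRP size, replenishment rate,
  and the uncorrected apparent release probability `y1 / y_intercept`.
* **Imaging** — delta-F images, histogram-based (Otsu) semi-automatic ROI
  segmentation of the cup-shaped terminal, delta-F/F extraction, and
  per-pulse AUC with closed-form overlap correction.
* **Deconvolution** — two release-rate estimators for reporter traces:
  frequency-domain Wiener deconvolution
  `X(f) = S(f) H*(f) / (|H|^2 + 1/SNR)` with a scalar SNR regularizer, and
  the linear-kernel estimator `s0 x(t) = ds/dt + s(t)/tau` with per-sample
  Gaussian error propagation.
* **Statistics** — origin-constrained regression with distance-to-identity
  `d`, Wilcoxon rank-sum (exact for small samples), Bonferroni-adjusted
  levels, a random-cell-intercept mixed model fitted by profiled maximum
  likelihood, and first-order error propagation.
* **A forward model** — binomial vesicle-pool depletion with Poisson
  refill, quantal currents, monoexponential reporter kinetics with exact
  exposure-window frame averaging, Poisson miniature events, and synthetic
  image stacks with a cup-shaped ROI; all seeded and byte-reproducible.

Results come back as tibbles; fitted objects support `tidy()`/`glance()`;
`autoplot()`, `plot_smn()` and `plot_readout_comparison()` give ggplot2
figures.

## Worked example

Simulate a 60 s miniature-EPSC recording at recording scale (127 pA
quanta, 7 Hz, 5 pA noise, 40 kHz), detect and summarize; then estimate
pool parameters from a 25 x 100 Hz train through both readouts:

```r
library(synaptoglu)

# miniature EPSCs
cfg <- synth_config(seed = 1)
rec <- simulate_minis(60, cfg)
events <- detect_minis(rec$ts)
summarize_cell(events, rec$ts)$summary
#>   n_events frequency median_amplitude median_charge median_tau median_fwhm
#> 1      401      6.68         1.21e-10      1.89e-14   0.000145    0.000101

# evoked train, electrical readout
prot <- stim_train(25, 100)
pool <- pool_model(n_rrp = 100, p_r = 0.3, refill_rate = 0)
train <- simulate_pool_train(prot, pool, mode = "deterministic")
epsc <- render_epsc(train$released, prot,
                    synth_config(pool = pool_model(quantal_tau = 0.33e-3)))
smn_analysis(measure_train(epsc$ts, prot), prot)
#>            rrp refill_rate p_apparent  y_intercept    slope
#> 1 0.0000000124    1.63e-12      0.306 0.0000000124 1.63e-11

# the same pool through the optical readout, deconvolved
prot_f <- stim_train(25, 100, t_start = 0.2)
train_f <- simulate_pool_train(prot_f, pool, mode = "deterministic")
fluo <- render_fluorescence(train_f$released, prot_f,
                            synth_config(noise_frames = 0))
dec <- linear_deconvolve(fluo$dff, tau = 38.43e-3)
y1_over_intercept(cumulative_release(dec, prot_f)$release)
#>   p_apparent y_intercept  slope
#> 1      0.301        248. 0.0862
```

Reading the numbers: the detector recovers 401 of ~420 planted events
(6.7 Hz observed), with median decay 0.145 ms and FWHM 0.101 ms — the
generative values. The electrical pool analysis back-extrapolates a
12.4 nA pool equivalent and an apparent release probability of 0.306; the
deconvolved optical readout of the same generative pool yields 0.301.
Both sit at the programmed `p_r = 0.3`, which is the point: the two
readout paths share one estimator and agree.

## Vignette

`vignettes/methods.Rmd` documents the models and their assumptions, every
tunable parameter with units and defaults, the numerical decisions
(midpoint evaluation in the linear deconvolution, release-window
alignment, fit rescaling, FWHM crossing rules), what the synthetic
generator does and does not emulate, and known limitations.
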