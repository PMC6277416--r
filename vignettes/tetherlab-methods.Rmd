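---
title: "tetherlab: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tetherlab: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherlab)
```

tetherlab quantifies the assembly state and dynamics of multi-subunit
vesicle-tethering complexes — the motivating system is the octameric
exocyst (SC1 = SEC3/5/6/8, SC2 = SEC10/15/EXO70/84) — from single-molecule
fluorescence data: dual-color FCCS in live cells, two-channel TIRF movies
of vesicle fusion, single-particle coincidence in lysate spreads, and
photobleaching-based molecule counting.  This vignette explains the models,
the estimators, the tunable parameters, and the choices made where the
design was genuinely open.

## The synthetic microscope

No deposited raw imaging accompanies the measurements this package
reproduces, so the `simgen` functions stand in for the instrument.  Every
generator records complete ground truth, which is what makes each analysis
stage testable end to end.

* `simulate_fcs_trace()` propagates point emitters by Brownian dynamics in
  a periodic box of 10 w~0~ per axis (large enough that the occupancy of
  the detection volume stays stationary), weights each by a 3D Gaussian
  detection profile exp(−2(x²+y²)/w₀² − 2z²/(s·w₀)²), and draws Poisson
  photon counts per bin.  Dual-labeled species emit in both channels from
  the same coordinates and therefore cross-correlate; independent species
  do not.
* `simulate_correlation_curves()` is the fast test path: it evaluates the
  closed-form correlation model on a quasi-logarithmic lag grid and adds
  heteroscedastic Gaussian noise with SD 0.03·|G(τ)| + 0.005·G(0) per
  curve — the replicate-to-replicate scatter scale of in-cell curves
  built from ≥10⁷ photons.
* `simulate_tirf_movie()` renders each fusion event as a diffraction-
  limited 2D Gaussian spot (σ ≈ 0.86 px, the 244 nm FWHM PSF on 120 nm
  pixels).  The subunit (green) trace steps up at arrival, persists with
  optional stepwise photobleaching, and steps down at departure; the
  pH-sensor (red) channel flashes at fusion with an instantaneous rise and
  an exponential decay over ~3 frames (the flash shape is not specified by
  the source measurements; this is the simplest kinetics with a sharp,
  datable onset).  Camera noise is Poisson shot noise plus Gaussian read
  noise.  Default arrival offsets are Normal(−14.6 s, 4 s) truncated below
  −2 s and departures Normal(1.4 s, 0.735 s); the medians are the
  published arrival/departure medians and the departure σ is back-derived
  from the published 95% CI (1.2–1.5 s at n = 145).
* `simulate_two_color_particles()` emulates a lysate spread: each reporter
  particle is bound with probability `bound_fraction`, its partner's dye
  is visible with probability `labeling_fraction` (Bernoulli labeling),
  green visibility follows the tagged-allele share, and unpaired red spots
  occur at `chance_density` per µm².

What the generators deliberately do **not** emulate: astigmatic/3D PSFs,
motion blur and within-frame exposure integration, camera-specific gain
maps, afterpulsing, and cellular background structure.  Passing tests
therefore demonstrate correctness of the estimators under idealized
optics, not robustness to every artifact of real data.

## The software correlator

`multiple_tau()` replaces the hardware correlator: lags sit on the
standard quasi-logarithmic grid (unit bin spacing for the first m = 16
channels, then the spacing doubles every m/2 channels), with symmetric
normalization

G(τ) = ⟨I_a(t) I_b(t+τ)⟩ / (⟨I_a⟩₍win₎ ⟨I_b⟩₍win₎) − 1,

each averaging window using its own mean.  Unlike a hardware correlator
there is **no data coarsening**: the estimator is evaluated exactly at
full trace resolution for every lag (affordable in software), so
`multiple_tau()` agrees with the brute-force `direct_correlation()` to
machine precision at every shared lag — a property the test suite asserts
at 1e-10.  Lags beyond an eighth of the trace duration are discarded by
default (estimator variance grows steeply there); both m and the cutoff
are arguments.

## The two-component FCCS model

Autocorrelations of each channel and the cross-correlation are fitted
jointly:

* G_j(τ) = G_j(0) · (f_D1 · Diff_D1j(τ) + f_D2 · Diff_D2(τ)), j = green, red
* G_x(τ) = G_x(0) · Diff_D2(τ)

with Diff(τ) = (1 + τ/τ_D)⁻¹ (1 + τ/(s²τ_D))^(−1/2) in 3D (cytosol) or
(1 + τ/τ_D)⁻¹ in 2D (membrane).  The cross curve carries only the slow,
co-diffusing component, and its residence time τ_D2 is a single shared
parameter with the slow component of both autocorrelations — the defining
constraint of the joint fit.  For singly labeled proteins f_D1/f_D2 are
mole fractions (f_D1 + f_D2 = 1).

`fit_fccs()` minimizes the SD-weighted residual sum of squares over the
three curves with Levenberg–Marquardt (`minpack.lm`), the same family of
optimizer the original analysis used.  Free parameters: three amplitudes,
f_D2, two fast residence times (per channel), and the shared τ_D2 — seven
in total.  τ values are optimized in log space with bound constraints;
τ_D2 is seeded from a log-spaced grid (10⁻⁴–1 s, lowest χ² wins) and
f_D2 starts at 0.5.  The aspect ratio s is held fixed at its calibrated
value during cell fits (the common FCCS practice; free only if the user
fits it via `calibrate_volume()`).

Derived quantities:

* D = w₀²/(4 τ_D) (`diffusion_from_tau()`), with w₀ from a reference-dye
  calibration (`calibrate_volume()` inverts the same relation).
* R_H = k_B T/(6πηD) (`hydrodynamic_radius()`), defaults T = 20 °C and
  η = 1.002 mPa·s (water).  At the published fast diffusion coefficient
  14.5 µm² s⁻¹ this gives 14.78 nm, matching the published fast-component
  radius 14.82 nm to 0.3%.  At the published slow coefficient
  0.54 µm² s⁻¹ the same formula gives ≈397 nm, whereas the published slow
  radius is a *median over per-measurement radii* (466 nm); because R_H is
  convex in D, the median of per-cell radii exceeds the radius at the mean
  D.  The package therefore computes per-measurement radii and reports
  both the median and the point value; users comparing to a single D
  should expect the difference.
* Coupling fractions from amplitudes: fraction of green bound =
  G_x(0)/G_r(0), fraction of red bound = G_x(0)/G_g(0)
  (`coupling_fractions()`), clipped to [0, 1] only with a warning.
* `crosstalk_correction()` removes the false cross-amplitude produced by
  green signal bleeding into the red channel under a linear bleedthrough
  model, solved exactly from the observed amplitudes and mean intensities.
  At realistic brightness ratios the correction is well below 0.1% of the
  fraction.  Fractions are deliberately *not* corrected for detection-
  volume mis-overlap (no reliable in-cell control), which can only
  underestimate all fractions by a common factor.

## Photobleaching steps and molecule counting

`detect_steps()` fits a piecewise-constant signal by exact least-squares
optimal partitioning (dynamic programming over all change-point
configurations).  The number of steps is chosen by a per-step penalty,
default 3·σ̂²·log n with σ̂ the noise SD from the median absolute first
difference — calibrated so the false-step rate on flat traces stays below
5% at SNR 5 while unit steps at SNR 5 are called reliably (the test suite
measures both).  A strictly positive penalty floor makes noiseless
staircases resolve to the minimal exact segmentation.

The initial intensity I₀ of a trace is the mean of its first plateau
(noise-robust, unlike a single-frame maximum).  `build_standard_curve()`
regresses I₀ on known copy number (1×/2×/3× tandem GFP fusions);
`count_molecules()` inverts the line and applies a ×2 heterozygosity
factor for cell lines with one tagged allele.

`peak_intensity()` measures spot amplitudes in images: spots closer than
4 px to a neighbour are excluded (Nyquist-style resolvability), the
background is the median over an annulus (radii configurable; the source
method leaves the background window unspecified), and the amplitude is the
Gaussian-interpolated peak — exact for a noiseless Gaussian profile.  The
brightest pre-fusion frame is selected by mean window intensity, and the
measurement is then taken in the *adjacent* frame: on a constant
pre-bleach plateau the expectation is identical but the noise is
independent of the selection, which removes the ~+4% extreme-value bias
that measuring in the selected frame itself would incur (a residual +~1%
interpolation bias at SNR ~20 remains; both numbers from simulation).

## Two-color coincidence

`detect_spots()` band-passes a frame with a difference of Gaussians at
scales matching the expected 0.27–0.35 µm spot diameters, takes local
maxima above a contrast threshold (default: 6×MAD of the filtered frame,
with a floor that keeps numerically-flat backgrounds clean), and refines
positions by 3×3 centroid.  `match_spots()` pairs channels by mutual
nearest neighbours within a radius, default 2 px ≈ 1 PSF σ (the source
states the detection diameter but not the matching radius; the radius is
an argument).  Each spot enters at most one pair; the test suite checks
match counts against a maximum-cardinality bipartite matching oracle.

`labeling_efficiency()` implements the per-field estimator
L_eff = mean(dye⁺ / (dye ∪ reporter)).  `fraction_bound()` corrects raw
coincidence for chance colocalization from a negative-control pair by the
renormalization (raw − f_c)/(1 − f_c) (the source states that a chance
control was used but not its arithmetic; renormalization is the standard
choice and is exposed), then divides by the dye labeling efficiency and
applies the heterozygosity factor, clipping to [0, 1].  A 3×3
(bound × labeling) simulation grid in the tests verifies recovery of the
true bound fraction within 0.05 absolute.

## Fusion-event timing

Fusion sites are found by spot detection on the maximum projection of the
pH-sensor channel; per-site ROI traces are then analysed.  A flash is a
sustained excursion above baseline + 3σ lasting ≥3 frames (the source
reviewed events visually; 3σ/3-frame is the package's numeric default),
and time zero is the flash *onset*, not its peak.  Subunit arrival and
departure are the boundaries of the sustained above-threshold run nearest
the fusion time.  All frame-boundary estimates use the midpoint
convention — the event is placed half a frame beyond the last frame on the
far side of the threshold — which removes the ±half-frame quantization
bias.  Baselines are estimated from the lower-decile cluster of the trace
with a first-difference noise SD, which stays correct even when the "on"
state occupies most of the trace.

`arrival_delay()` compares two channels of the same event after
normalizing each to [0, 1]: the half-maximum crossing is refined below the
frame time by linear interpolation, which is what makes sub-frame delays
(e.g. a 77 ms median at an 80 ms frame time) representable at all.
Events are classed simultaneous when |delay| < one frame interval.
`summarize_events()` reports medians with seeded percentile-bootstrap 95%
CIs (default 10⁴ resamples) and refuses fewer than 5 events.

## Tracking and diffusivity

`link_tracks()` links detections frame to frame by mutual nearest
neighbours within a maximum displacement, with optional gap closing;
crossing particles farther apart than the radius break rather than swap.
`msd()` computes time-averaged MSD per track; `ensemble_msd()` combines
tracks by geometric mean (mirroring how ensemble MSD curves are usually
displayed for skewed per-track distributions) or arithmetic mean.
`fit_diffusion()` fits ⟨r²⟩ = 4Dτ + c over the first 4 lags with a free
intercept that absorbs static localization noise — the standard
bias/variance compromise; the lag count is an argument.  Diffusion
fitting uses the *arithmetic* ensemble (the unbiased estimator); the
geometric mean is for display.  `membrane_localization_index()` is the
product of spot density and mean cell intensity (arbitrary units —
spots·µm⁻²·ADU; the index has no canonical unit).

## The state-abundance model

With nested colocalization (every octamer contains SC1), pairwise
couplings convert to state abundances:
octamer = f(SEC5+EXO70); SC1 tetramer = f(SEC5+SEC8) − f(SEC5+EXO70);
free = 100 − octamer − tetramer; free SEC3 = 100 − f(SEC3+SEC5).
An input pair with f(SEC5+SEC8) < f(SEC5+EXO70) violates the nesting
premise and is an error, not a clip.  Two measured input sets ship as
presets: `cytosol_fccs` (92/64/67%) and `membrane_tirf` (85/60/60%) —
they give 64/28/8% and 60/25/15% respectively, bracketing the ~65/25/10%
summary figure; no single printed input pair reproduces that summary
exactly, which is why both presets are reported side by side.
`propagate_uncertainty()` propagates input SEMs by Monte Carlo with
percentile CIs, dropping (and counting) draws that violate the nesting
order.

## Problem sizes, tolerances, degenerate inputs

Simulation sizes used by the tests and the acceptance script are the
study's own scales where printed (25 FCCS replicates; 20 fields × 500
particles; 50 traces per calibration class; 50 vesicle-site spots; 500
tracks × 100 steps at 12.5 Hz; 100 fusion events at 5 Hz), with trace
durations chosen so each run completes in seconds.  For the
published-median recovery runs the drawn offsets/copies are recentred so
the realized sample median (or mean) equals the published value exactly —
the quantity under test is the measurement pipeline, and recentring keeps
Monte-Carlo scatter of the ground truth out of the comparison.

Numerical edge cases are handled explicitly: constant-zero traces are a
normalization error in the correlator; D ≤ 0 and τ_D ≤ 0 are rejected;
negative molecule counts clip to zero with a warning; traces that never
cross threshold yield NA events; departures at the last frame are flagged
right-censored; single-replicate curve sets carry NA per-lag SDs and
trigger uniform-weight fitting with a message.

## Known limitations

The FCCS model omits triplet-state kinetics (absent from the model being
reproduced) and photon-arrival correlation.  Spot detection assumes
registered channels (hardware splitter alignment) and does not compute
pixel-correlation coefficients.  Anomalous-diffusion exponents are not
fitted.  The state model is an equilibrium bookkeeping identity, not a
kinetic model.  All recovery results are under the idealized optics of the
generators, as noted above.
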