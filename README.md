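# tetherlab

Single-molecule and fluorescence-fluctuation analysis of vesicle-tethering
complex dynamics.

## What this package is for

Multi-subunit tethering complexes such as the exocyst (eight subunits in
two subcomplexes, SC1 = SEC3/5/6/8 and SC2 = SEC10/15/EXO70/84) dock
secretory vesicles at the plasma membrane.  Whether such a complex exists
as a stable octamer or as an equilibrium of subcomplexes and free subunits
— and how many copies tether each vesicle — can be measured in live cells
with single-molecule fluorescence, but the analyses involved span several
specialised methods.  tetherlab implements that tool chain for R users:

* **Software multiple-tau correlator** (`multiple_tau`,
  `direct_correlation`): quasi-logarithmic lag grid, symmetric
  normalization, exact at every lag.
* **Dual-color FCCS model fitting** (`fit_fccs`): joint weighted
  Levenberg–Marquardt fit of green/red autocorrelations and the
  cross-correlation with a two-component diffusion model,
  G_j(τ) = G_j(0)(f_D1·Diff_D1j(τ) + f_D2·Diff_D2(τ)) and
  G_x(τ) = G_x(0)·Diff_D2(τ), the slow residence time shared across the
  three curves.  Derived: D = w₀²/4τ_D, Stokes–Einstein R_H = k_BT/6πηD,
  and coupling fractions G_x(0)/G_r(0), G_x(0)/G_g(0), with spectral
  cross-talk correction.
* **Photobleaching step counting and molecule counting** (`detect_steps`,
  `build_standard_curve`, `peak_intensity`, `count_molecules`):
  change-point detection by penalized optimal partitioning, a 1×/2×/3×-GFP
  standard curve, and conversion of vesicle-site peak intensities into
  copy numbers.
* **Two-color coincidence** (`detect_spots`, `match_spots`,
  `labeling_efficiency`, `fraction_bound`): spot detection, mutual-
  nearest-neighbour matching, and bound-fraction estimates corrected for
  dye labeling efficiency, heterozygous tagging and chance colocalization.
* **Fusion-event timing** (`detect_fusion_flashes`, `arrival_departure`,
  `arrival_delay`, `summarize_events`, `measure_fusion_events`): pH-sensor
  flash detection, subunit arrival/departure relative to fusion,
  sub-frame two-channel arrival delays, bootstrap summaries.
* **Tracking and diffusivity** (`link_tracks`, `msd`, `ensemble_msd`,
  `fit_diffusion`): MSD-based diffusion coefficients from particle
  trajectories, ⟨r²⟩ = 4Dτ over the first lags.
* **State-abundance model** (`state_abundances`,
  `propagate_uncertainty`): converts pairwise couplings into
  octamer / SC1-tetramer / free-subunit percentages.
* **Synthetic microscope** (`simulate_fcs_trace`, `simulate_tirf_movie`,
  `simulate_two_color_particles`, `simulate_brownian_tracks`,
  `simulate_bleach_traces`, `simulate_correlation_curves`): generators
  with full ground truth for every observable, so the entire pipeline is
  testable without instrument data.

## Worked example

Simulate 25 replicate FCCS curve triplets for a strongly coupled subunit
pair (92% of the green-labeled species bound, slow/fast diffusion 0.54 and
14.5 µm² s⁻¹), fit the joint model, and read off the coupling:

```r
library(tetherlab)

vol   <- detection_volume(w0 = 0.25, s = 5)
truth <- fccs_params(G_g0 = 0.5, G_r0 = 0.4, G_x0 = 0.92 * 0.4,
                     f_D2 = 0.49, tau_D1g = 1.08e-3, tau_D1r = 1.08e-3,
                     tau_D2 = 2.89e-2)
reps <- simulate_correlation_curves(truth, vol, n_replicates = 25, seed = 1)
fit  <- fit_fccs(reps[[1]]$green, reps[[1]]$red, reps[[1]]$cross, volume = vol)
fit
#> Two-component FCCS joint fit (3d)
#>   amplitudes G_g0 = 0.5029, G_r0 = 0.4056, G_x0 = 0.3672
#>   f_slow = 0.486; tau_D1(g,r) = 0.00107, 0.000925 s; tau_D2 = 0.0294 s
#>   D_fast(g,r) = 14.6, 16.9; D_slow = 0.531 um^2/s
#>   R_H fast = 13.6 nm, slow = 403 nm
#>   bound fractions: green = 0.905, red = 0.730
#>   chi-square = 285.1 on 317 dof (4 iterations)
```

One replicate recovers the generating coupling (0.92) to ~1.5%; averaging
the 25 replicate fits recovers it to ~0.2%.  `f_slow` is the mole fraction
of the slow co-diffusing component, `tau_D2` its residence time in the
detection volume, and the hydrodynamic radii follow from Stokes–Einstein
at 20 °C in water.

Feeding measured pairwise couplings into the state model (here the
membrane coincidence preset: SEC5+SEC8 85%, SEC5+EXO70 60%):

```r
do.call(state_abundances, state_preset("membrane_tirf"))
#> state_abundances: octamer 60.0%, SC1 tetramer 25.0%, free 15.0% (free SEC3 40.0%)
```

i.e. at the membrane ~60% of subunits sit in complete octamers, ~25% of
SC1 exists as a free tetramer, and ~15% of subunits are unassembled.

## Layout

```
R/                   implementation (one file per analysis domain)
tests/testthat/      unit, property and acceptance tests
scripts/acceptance.R end-to-end reproduction script
vignettes/           methods vignette (models, estimators, design choices)
```
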