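test_that("diffusion terms obey their limiting values", {
  expect_equal(diff_term_3d(0, 0.01, 5), 1)
  expect_equal(diff_term_2d(0, 0.01), 1)
  expect_equal(diff_term_2d(0.01, 0.01), 0.5)
  # very elongated volume: 3D term approaches the 2D form
  tau <- c(0.001, 0.01, 0.1)
  expect_equal(diff_term_3d(tau, 0.01, 1e6), diff_term_2d(tau, 0.01),
               tolerance = 1e-9)
  expect_error(diff_term_3d(0.01, -1, 5), "tau_D")
  expect_error(diff_term_2d(0.01, 0), "tau_D")
})

test_that("model evaluation collapses correctly at its edges", {
  vol <- default_volume()
  p1 <- fccs_params(0.5, 0.4, 0.3, f_D2 = 1, tau_D1g = 1e-3,
                    tau_D1r = 1e-3, tau_D2 = 0.03)
  tau <- c(0, 0.001, 0.01, 0.1)
  # pure slow component: auto curve is single-component
  expect_equal(eval_fccs_model(tau, p1, "green", vol),
               0.5 * diff_term_3d(tau, 0.03, vol$s))
  # cross amplitude at zero lag
  expect_equal(eval_fccs_model(0, p1, "cross", vol), 0.3)
  expect_error(eval_fccs_model(tau, p1, "purple", vol))
})

test_that("D = w0^2 / 4 tau_D and its round trips", {
  expect_equal(diffusion_from_tau(0.01, 0.2), 1.0)
  # monotone decreasing in tau_D
  expect_true(all(diff(diffusion_from_tau(c(0.01, 0.02, 0.04), 0.25)) < 0))
  expect_error(diffusion_from_tau(-1, 0.2))
})

test_that("Stokes-Einstein radius matches the closed form and scales as 1/D", {
  cst <- physical_constants()
  closed_form <- function(D)
    cst$k_B * cst$T_K / (6 * pi * cst$eta_Pa_s * D * 1e-12) * 1e9
  for (D in c(0.54, 5, 14.5))
    expect_equal(hydrodynamic_radius(D), closed_form(D), tolerance = 1e-12)
  expect_equal(hydrodynamic_radius(2) / hydrodynamic_radius(4), 2,
               tolerance = 1e-12)
  expect_error(hydrodynamic_radius(0))
})

test_that("coupling fractions are amplitude ratios with [0,1] clipping", {
  expect_equal(unname(coupling_fractions(0.5, 0.4, 0)), c(0, 0))
  expect_equal(unname(coupling_fractions(0.3, 0.3, 0.3)), c(1, 1))
  expect_warning(fr <- coupling_fractions(0.2, 0.2, 0.3), "clipped")
  expect_true(all(fr <= 1))
})

test_that("cross-talk correction removes bleedthrough-induced coupling", {
  expect_warning(  # clipped exactly at 1 is fine; identity at kappa = 0
    fr0 <- crosstalk_correction(0.4, 0.4, 0.4, 100, 100, 0)$fractions,
    regexp = NA)
  expect_equal(unname(fr0), c(1, 1))
  expect_error(crosstalk_correction(0.4, 0.4, 0.2, 100, 100, 1), "bleedthrough")

  # two independent species, red channel contaminated by 1% of green:
  # simulate, correlate, and check the corrected cross amplitude is ~0
  vol <- default_volume()
  sp_g <- species_spec(D = 5, concentration = 1, brightness_g = 5e4)
  sp_r <- species_spec(D = 5, concentration = 1, brightness_r = 5e4)
  tr <- simulate_fcs_trace(list(sp_g, sp_r), vol, duration = 8,
                           bin_dt = 2e-4, seed = 31)
  kappa <- 0.01
  mixed <- intensity_trace(cbind(green = tr$values[, "green"],
                                 red = tr$values[, "red"] +
                                   kappa * tr$values[, "green"]),
                           tr$bin_dt)
  amp <- function(curve) mean(curve$G[1:4])
  G_g0 <- amp(multiple_tau(mixed, "green"))
  G_r0 <- amp(multiple_tau(mixed, "red"))
  G_x0 <- max(amp(multiple_tau(mixed, "green", "red")), 0)
  raw <- coupling_fractions(G_g0, G_r0, G_x0)
  corr <- crosstalk_correction(G_g0, G_r0, G_x0,
                               mean(mixed$values[, "green"]),
                               mean(mixed$values[, "red"]), kappa)
  expect_lt(corr$fractions[["green"]], raw[["green"]] + 1e-12)
  expect_lt(corr$fractions[["green"]], 0.05)
})

test_that("noise-free curve triplets are fitted exactly", {
  p <- cell_params()
  vol <- default_volume()
  reps <- suppressWarnings(simulate_correlation_curves(
    p, vol, n_replicates = 1, noise_rel = 0, noise_floor = 0, seed = 1))
  fit <- suppressMessages(
    fit_fccs(reps[[1]]$green, reps[[1]]$red, reps[[1]]$cross, volume = vol))
  for (nm in c("G_g0", "G_r0", "G_x0", "f_D2", "tau_D1g", "tau_D1r", "tau_D2"))
    expect_rel_equal(fit$params[[nm]], p[[nm]], 1e-6)
  expect_rel_equal(fit$fraction_green_bound, 0.92, 1e-6)
})

test_that("the cross curve shares the slow residence time of the auto curves", {
  p <- cell_params()
  vol <- default_volume()
  reps <- simulate_correlation_curves(p, vol, n_replicates = 3, seed = 5)
  fit <- fit_fccs(reps[[1]]$green, reps[[1]]$red, reps[[1]]$cross, volume = vol)
  # single shared tau_D2 by construction of the joint model: the slow time
  # used for the cross curve IS params$tau_D2 (hard assertion)
  expect_equal(
    eval_fccs_model(reps[[1]]$cross$lag, fit$params, "cross", vol) /
      fit$params$G_x0,
    diff_term_3d(reps[[1]]$cross$lag, fit$params$tau_D2, vol$s),
    tolerance = 1e-12)
})

test_that("fit chi-square minimum agrees with a brute-force grid search", {
  p <- cell_params()
  vol <- default_volume()
  reps <- simulate_correlation_curves(p, vol, n_replicates = 5, seed = 17)
  r <- reps[[1]]
  fit <- fit_fccs(r$green, r$red, r$cross, volume = vol)
  # oracle: amplitudes fixed at the fitted values, shared fast time;
  # exhaustive grid over (f_D2, tau_D1, tau_D2)
  sds <- lapply(r, function(cv) cv$sd)
  chisq_at <- function(f2, td1, td2) {
    q <- fccs_params(fit$params$G_g0, fit$params$G_r0, fit$params$G_x0,
                     f_D2 = f2, tau_D1g = td1, tau_D1r = td1, tau_D2 = td2)
    sum(((r$green$G - eval_fccs_model(r$green$lag, q, "green", vol)) / sds$green)^2) +
      sum(((r$red$G - eval_fccs_model(r$red$lag, q, "red", vol)) / sds$red)^2) +
      sum(((r$cross$G - eval_fccs_model(r$cross$lag, q, "cross", vol)) / sds$cross)^2)
  }
  grid <- expand.grid(f2 = seq(0.40, 0.60, by = 0.01),
                      td1 = exp(seq(log(5e-4), log(3e-3), length.out = 25)),
                      td2 = exp(seq(log(1e-2), log(8e-2), length.out = 25)))
  cs <- mapply(chisq_at, grid$f2, grid$td1, grid$td2)
  best <- grid[which.min(cs), ]
  # the LM optimum is at least as good as the best grid point, and the grid
  # argmin lands within one grid step of the LM solution
  expect_lte(fit$chisq, min(cs) * (1 + 1e-9))
  expect_lt(abs(best$f2 - fit$params$f_D2), 0.011)
  expect_lt(abs(log(best$td2 / fit$params$tau_D2)), log(8e-2 / 1e-2) / 24)
})

test_that("parameters are recovered across seeded replicates at study noise", {
  p <- cell_params()
  vol <- default_volume()
  reps <- simulate_correlation_curves(p, vol, n_replicates = 25, seed = 23)
  fits <- lapply(reps, function(r)
    fit_fccs(r$green, r$red, r$cross, volume = vol))
  med <- function(get) median(vapply(fits, get, numeric(1)))
  expect_rel_equal(med(function(f) f$params$f_D2), 0.49, 0.05)
  expect_rel_equal(med(function(f) f$params$tau_D2), p$tau_D2, 0.05)
  expect_rel_equal(med(function(f) f$fraction_green_bound), 0.92, 0.05)
})

test_that("volume calibration recovers w0 from a reference dye", {
  # free dye at D = 400 um^2/s in a 0.25 um volume
  w0 <- 0.25
  p <- fccs_params(0.4, 0.4, 0, f_D2 = 1, tau_D1g = 1e-5, tau_D1r = 1e-5,
                   tau_D2 = w0^2 / (4 * 400))
  reps <- simulate_correlation_curves(
    p, detection_volume(w0, 5), lag = fcs_lag_grid(2e-6, 0.1),
    n_replicates = 3, noise_rel = 0.01, noise_floor = 0.001, seed = 3)
  cal <- calibrate_volume(average_curves(lapply(reps, `[[`, "green")),
                          D_known = 400)
  expect_rel_equal(cal$w0, w0, 0.05)
  # tau_D scales with w0^2
  expect_equal(diffusion_from_tau(attr(cal, "tau_D"), cal$w0), 400,
               tolerance = 1e-6)
  # a 2D reference leaves s undefined
  p2 <- fccs_params(0.4, 0.4, 0, f_D2 = 1, tau_D1g = 1e-3, tau_D1r = 1e-3,
                    tau_D2 = 0.02, dimensionality = "2d")
  r2 <- suppressWarnings(simulate_correlation_curves(
    p2, n_replicates = 1, noise_rel = 0.005, noise_floor = 5e-4, seed = 4))
  expect_message(cal2 <- calibrate_volume(r2[[1]]$green, D_known = 1,
                                          dimensionality = "2d"),
                 "undefined")
  expect_true(is.na(cal2$s))
  # a hopeless reference (oscillating, not a diffusion decay) is rejected
  lag_bad <- 10^seq(-4, -1, length.out = 40)
  bad <- correlation_curve(lag_bad, 0.4 + 0.2 * sin(seq_len(40)))
  expect_error(calibrate_volume(bad, D_known = 400), "rejected")
})

test_that("trace -> correlator -> fit chain reproduces the input D and R_H", {
  vol <- default_volume()
  D_true <- 5
  sp <- species_spec(D = D_true, concentration = 2, brightness_g = 8e4)
  tr <- simulate_fcs_trace(list(sp), vol, duration = 10, bin_dt = 2e-4,
                           seed = 3)
  cal <- calibrate_volume(multiple_tau(tr, "green"), D_known = D_true,
                          max_rel_residual = 0.2)
  D_fit <- diffusion_from_tau(attr(cal, "tau_D"), vol$w0)
  expect_rel_equal(D_fit, D_true, 0.2)
  expect_rel_equal(hydrodynamic_radius(D_fit), hydrodynamic_radius(D_true),
                   0.25)
})
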