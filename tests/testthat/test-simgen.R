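test_that("Brownian increments have the closed-form variance 2 D dt", {
  D <- 0.31; dt <- 0.08
  tr <- simulate_brownian_tracks(400, D, dt, n_steps = 50, seed = 12)
  dx <- unlist(lapply(split(tr$x_um, tr$track_id), diff))
  n <- length(dx)
  expect_rel_equal(var(dx), 2 * D * dt, 4 * sqrt(2 / n))
  # increments are Gaussian
  expect_gt(stats::shapiro.test(sample(dx, 3000))$p.value, 0.001)
})

test_that("degenerate and invalid diffusion inputs are handled", {
  tr <- simulate_brownian_tracks(3, D = 0, dt = 0.1, n_steps = 10, seed = 1)
  expect_true(all(tr$x_um == 0) && all(tr$y_um == 0))
  expect_error(simulate_brownian_tracks(3, 1, dt = 0, n_steps = 10), "dt")
  expect_error(simulate_brownian_tracks(3, 1, dt = 0.1, n_steps = 0),
               "n_steps")
})

test_that("a fixed seed reproduces simulations bit for bit", {
  a <- simulate_brownian_tracks(5, 0.3, 0.08, 20, seed = 99)
  b <- simulate_brownian_tracks(5, 0.3, 0.08, 20, seed = 99)
  expect_identical(a, b)
  fa <- simulate_two_color_particles(50, 0.5, 0.4, seed = 99)
  fb <- simulate_two_color_particles(50, 0.5, 0.4, seed = 99)
  expect_identical(fa, fb)
  ma <- simulate_tirf_movie(4, duration = 50,
                            config = sim_config(seed = 99, frame_dt = 0.2))
  mb <- simulate_tirf_movie(4, duration = 50,
                            config = sim_config(seed = 99, frame_dt = 0.2))
  expect_identical(ma$green, mb$green)
  expect_identical(ma$ground_truth, mb$ground_truth)
})

test_that("an immobile emitter gives a constant expected intensity", {
  vol <- default_volume()
  sp <- species_spec(D = 1e-9, concentration = 1 / (10 * vol$w0)^3,
                     brightness_g = 1e4)
  tr <- simulate_fcs_trace(list(sp), vol, duration = 0.2, bin_dt = 1e-3,
                           seed = 2, shot_noise = FALSE)
  expect_lt(diff(range(tr$values[, "green"])) /
              max(mean(tr$values[, "green"]), 1e-12), 1e-4)
})

test_that("channels without a dual-labeled species do not cross-correlate", {
  vol <- default_volume()
  sp_g <- species_spec(D = 10, concentration = 1, brightness_g = 5e4)
  sp_r <- species_spec(D = 10, concentration = 1, brightness_r = 5e4)
  tr <- simulate_fcs_trace(list(sp_g, sp_r), vol, duration = 8,
                           bin_dt = 2e-4, seed = 13)
  gx <- multiple_tau(tr, "green", "red")
  gg <- multiple_tau(tr, "green")
  expect_lt(abs(mean(gx$G[1:10])), 0.1 * mean(gg$G[1:10]))
  expect_error(simulate_fcs_trace(list(), vol, 1, 1e-3), "non-empty")
})

test_that("trace mean intensity matches concentration x volume x brightness", {
  vol <- default_volume()
  conc <- 5; Bg <- 2e4; dur <- 6; bdt <- 5e-4
  tr <- simulate_fcs_trace(list(species_spec(D = 20, concentration = conc,
                                             brightness_g = Bg)),
                           vol, duration = dur, bin_dt = bdt, seed = 21)
  # integral of the 3D Gaussian detection profile
  V_eff_integral <- (pi / 2)^(3 / 2) * vol$w0^3 * vol$s
  L <- 10 * vol$w0
  n_p <- round(conc * L^3)
  expected <- n_p * (V_eff_integral / L^3) * Bg * bdt
  expect_rel_equal(mean(tr$values[, "green"]), expected, 0.15)
})

test_that("noiseless simulated curves equal the model exactly", {
  p <- cell_params()
  vol <- default_volume()
  reps <- suppressWarnings(simulate_correlation_curves(
    p, vol, n_replicates = 1, noise_rel = 0, noise_floor = 0, seed = 1))
  for (w in c("green", "red", "cross"))
    expect_equal(reps[[1]][[w]]$G,
                 eval_fccs_model(reps[[1]][[w]]$lag, p, w, vol),
                 tolerance = 1e-12)
  expect_warning(simulate_correlation_curves(p, vol, n_replicates = 1),
                 "single replicate")
  expect_error(simulate_correlation_curves(p, vol, noise_rel = -1),
               ">= 0")
})

test_that("movie events render at their ground-truth times and positions", {
  cfg <- sim_config(seed = 41, frame_dt = 0.2,
                    noise = list(photon = FALSE, read_sd = 0))
  mv <- simulate_tirf_movie(1, duration = 50, config = cfg)
  gt <- mv$ground_truth
  red_tr <- extract_roi_trace(mv$red, gt$x_px, gt$y_px, 3)
  fl <- detect_fusion_flashes(red_tr, mv$frame_times)
  # noiseless: onset frame is exactly the first frame after the fusion time
  expect_identical(fl$onset_frame,
                   which(mv$frame_times >= gt$t_fusion)[1])
  green_tr <- extract_roi_trace(mv$green, gt$x_px, gt$y_px, 3)
  on <- which(green_tr > mv$background + 1)
  expect_identical(min(on), which(mv$frame_times >= gt$t_arrival)[1])
})

test_that("overcrowded movies and impossible offsets are rejected", {
  expect_error(simulate_tirf_movie(500, img_size = c(32, 32), duration = 50,
                                   config = sim_config(seed = 1, frame_dt = 0.2)),
               "density")
  expect_error(simulate_tirf_movie(2, duration = 50,
                                   arrival_offset = function(n) rep(5, n),
                                   departure_offset = function(n) rep(1, n),
                                   config = sim_config(seed = 1, frame_dt = 0.2)),
               "exceed")
})

test_that("two-color particle fields respect their generating fractions", {
  # complete binding and labeling: every green spot has a red partner
  f <- simulate_two_color_particles(300, 1, 1, chance_density = 0, seed = 6)
  m <- match_spots(f$green, f$red, radius_px = 2)
  expect_equal(nrow(m), nrow(f$green))
  # no labeling: no red spots at all
  f0 <- simulate_two_color_particles(300, 1, 0, chance_density = 0, seed = 6)
  expect_identical(nrow(f0$red), 0L)
  expect_error(simulate_two_color_particles(10, 1.2, 0.4), "\\[0, 1\\]")
  # ground truth covers every particle
  expect_identical(nrow(f$truth), 300L)
})
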