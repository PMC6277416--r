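make_times <- function(n, dt = 0.2) (seq_len(n) - 0.5) * dt

test_that("a synthetic flash is dated at its onset frame", {
  tt <- make_times(200)
  x <- rep(10, 200); x[100:105] <- c(300, 200, 130, 90, 60, 40)
  fl <- detect_fusion_flashes(x + 0, tt)
  expect_identical(fl$onset_frame, 100L)
  expect_equal(fl$t_fusion, tt[100] - 0.1)
})

test_that("flat noise yields no flashes at a 5-sigma threshold", {
  set.seed(5)
  tt <- make_times(300)
  x <- rnorm(300, 50, 5)
  expect_identical(nrow(detect_fusion_flashes(x, tt, k_sigma = 5)), 0L)
})

test_that("flashes at the trace start are skipped for lack of baseline", {
  tt <- make_times(100)
  x <- rep(10, 100); x[5:9] <- 500; x[60:64] <- 500
  expect_message(fl <- detect_fusion_flashes(x, tt), "skipped")
  expect_identical(fl$onset_frame, 60L)
})

test_that("arrival/departure are exact arithmetic on a clean step trace", {
  dt <- 0.2
  tt <- make_times(400, dt)
  t_fus <- tt[200] - dt / 2            # fusion exactly at a frame boundary
  t_arr_true <- t_fus - 14.6           # arrival 14.6 s before fusion
  t_dep_true <- t_fus + 1.4
  x <- ifelse(tt >= t_arr_true & tt <= t_dep_true, 100, 0) + 0
  ad <- arrival_departure(x, t_fus, tt)
  expect_lt(abs(ad$t_arrival - (-14.6)), dt / 2 + 1e-9)
  expect_lt(abs(ad$t_departure - 1.4), dt / 2 + 1e-9)
  expect_equal(ad$residence, ad$t_departure - ad$t_arrival)
  expect_false(ad$right_censored)
})

test_that("estimators are translation-equivariant in time", {
  set.seed(6)
  dt <- 0.2
  tt <- make_times(400, dt)
  x <- ifelse(tt >= 20 & tt <= 36, 100, 0) + rnorm(400, 0, 5)
  a1 <- arrival_departure(x, 34, tt)
  a2 <- arrival_departure(x, 34 + 7, tt + 7)
  expect_equal(a1, a2)
})

test_that("censoring and absent events are reported", {
  tt <- make_times(100)
  x <- ifelse(tt >= 15, 100, 0) + 0
  ad <- arrival_departure(x, 18, tt)
  expect_true(ad$right_censored)
  flat <- rep(5, 100)
  expect_true(is.na(arrival_departure(flat, 10, tt)$t_arrival))
})

test_that("arrival delays resolve below the frame time by interpolation", {
  dt <- 0.08                           # 12.5 Hz
  tt <- make_times(250, dt)
  ramp <- function(t0) pmin(pmax((tt - t0) / (3 * dt), 0), 1) * 100
  # identical traces: zero delay, simultaneous
  d0 <- arrival_delay(ramp(8), ramp(8), tt)
  expect_equal(d0$delay_ms, 0, tolerance = 1e-9)
  expect_identical(d0$order_class, "simultaneous")
  # one-frame shift at 12.5 Hz = +80 ms, channel 2 second
  d1 <- arrival_delay(ramp(8), ramp(8 + dt), tt)
  expect_equal(d1$delay_ms, 80, tolerance = 1e-6)
  expect_identical(d1$order_class, "second")
  # sub-frame shift recovered by interpolation
  d2 <- arrival_delay(ramp(8), ramp(8 + 0.077), tt)
  expect_equal(d2$delay_ms, 77, tolerance = 1)
  # unpaired event: one channel never rises
  expect_true(is.na(arrival_delay(ramp(8), 0 * tt, tt)$delay_ms))
})

test_that("simulated delay distributions recover their median", {
  set.seed(7)
  dt <- 0.08
  tt <- make_times(250, dt)
  ramp <- function(t0) pmin(pmax((tt - t0) / (3 * dt), 0), 1) * 100 +
    rnorm(length(tt), 0, 3)
  lags_ms <- rnorm(60, 77, 30)
  delays <- vapply(lags_ms, function(L)
    arrival_delay(ramp(8), ramp(8 + L / 1000), tt)$delay_ms, numeric(1))
  sm <- summarize_events(data.frame(delay_ms = delays), seed = 1)
  truth_med <- median(lags_ms)
  boot_se <- (sm$medians$ci_hi - sm$medians$ci_lo) / (2 * 1.96)
  expect_lt(abs(sm$medians$median - truth_med), 2 * boot_se)
})

test_that("event summaries refuse tiny samples and report textbook medians", {
  expect_error(summarize_events(1:4), "fewer than 5")
  sm <- summarize_events(c(5, 1, 9, 3, 7), seed = 2)
  expect_equal(sm$medians$median, 5)
  ev <- data.frame(delay_ms = rnorm(20),
                   order_class = rep(c("first", "second"), 10))
  expect_equal(unname(summarize_events(ev, seed = 3)$order_class["first"]),
               0.5)
})

test_that("bootstrap CIs cover the generating median at nominal rate", {
  covered <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(40, 1.4, 0.7)
    sm <- summarize_events(x, n_boot = 400, seed = s)
    if (sm$medians$ci_lo <= 1.4 && 1.4 <= sm$medians$ci_hi)
      covered <- covered + 1
  }
  expect_gte(covered, 93)
})

test_that("the movie pipeline recovers event timing with high recall", {
  mv <- simulate_tirf_movie(25, duration = 70,
                            config = sim_config(seed = 71, frame_dt = 0.2))
  ev <- measure_fusion_events(mv)
  expect_gte(nrow(ev), ceiling(0.95 * 25))
  gt <- mv$ground_truth
  expect_lt(abs(median(ev$t_arrival) -
                  median(gt$t_arrival - gt$t_fusion)), 0.4)
  expect_lt(abs(median(ev$t_departure) -
                  median(gt$t_departure - gt$t_fusion)), 0.4)
})

test_that("recovered residence times match the generating distribution", {
  mv <- simulate_tirf_movie(60, duration = 80,
                            config = sim_config(seed = 72, frame_dt = 0.2))
  ev <- measure_fusion_events(mv)
  gt <- mv$ground_truth
  ks <- suppressWarnings(
    stats::ks.test(ev$residence, gt$t_departure - gt$t_arrival))
  expect_gt(ks$p.value, 0.01)
})
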