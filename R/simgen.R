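#' Acquisition configuration for synthetic imaging
#'
#' Defaults mirror a fast TIRF acquisition: 12.5 Hz frame rate, 120 nm
#' pixels, and a diffraction-limited PSF of 244 nm FWHM (sigma ~0.86 px).
#'
#' @param seed integer seed fixing all randomness of a simulation call.
#' @param frame_dt frame interval in seconds (default 0.08 s = 12.5 Hz).
#' @param pixel_size pixel size in micrometres (default 0.12).
#' @param psf_sigma_px lateral Gaussian PSF sigma in pixels
#'   (default 0.244/2.355/0.12).
#' @param noise list with `photon` (logical: apply Poisson shot noise) and
#'   `read_sd` (Gaussian read noise SD in ADU).
#' @export
sim_config <- function(seed = 1L, frame_dt = 0.08, pixel_size = 0.12,
                       psf_sigma_px = 0.244 / 2.355 / 0.12,
                       noise = list(photon = TRUE, read_sd = 2)) {
  stopifnot(frame_dt > 0, pixel_size > 0, psf_sigma_px > 0,
            is.list(noise), noise$read_sd >= 0)
  structure(list(seed = as.integer(seed), frame_dt = frame_dt,
                 pixel_size = pixel_size, psf_sigma_px = psf_sigma_px,
                 noise = noise), class = "sim_config")
}

#' Diffusing species for fluctuation-trace simulation
#'
#' @param D diffusion coefficient, micrometres squared per second (> 0).
#' @param concentration particles per cubic micrometre (3D) or per square
#'   micrometre (2D).
#' @param brightness_g,brightness_r detected photons per second per molecule
#'   in the green / red channel (>= 0, at least one > 0).
#' @param dual_labeled logical; a dual-labeled species carries both
#'   fluorophores on the same particle and therefore cross-correlates.
#' @export
species_spec <- function(D, concentration, brightness_g = 0, brightness_r = 0,
                         dual_labeled = brightness_g > 0 && brightness_r > 0) {
  stopifnot(D > 0, concentration > 0,
            brightness_g >= 0, brightness_r >= 0,
            brightness_g > 0 || brightness_r > 0)
  if (dual_labeled && (brightness_g <= 0 || brightness_r <= 0))
    stop("a dual-labeled species needs positive brightness in both channels")
  structure(list(D = D, concentration = concentration,
                 brightness_g = brightness_g, brightness_r = brightness_r,
                 dual_labeled = dual_labeled), class = "species_spec")
}

#' Simulate free Brownian tracks
#'
#' Position increments per axis are independent Gaussian with variance
#' 2 D dt, the defining property of free diffusion; positions are in
#' micrometres.
#'
#' @param n_tracks number of tracks.
#' @param D diffusion coefficient, micrometres squared per second (>= 0;
#'   D = 0 gives stationary tracks).
#' @param dt time step, seconds (> 0).
#' @param n_steps number of steps per track (> 0); each track has
#'   `n_steps + 1` positions.
#' @param dim spatial dimension, 2 or 3.
#' @param seed integer seed.
#' @param origin starting position (recycled per axis), default 0.
#' @return data.frame `{track_id, frame, x_um, y_um[, z_um]}` with attribute
#'   `ground_truth` = list(D = D, dt = dt).
#' @export
simulate_brownian_tracks <- function(n_tracks, D, dt, n_steps, dim = 2,
                                     seed = 1L, origin = 0) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (!is.numeric(n_steps) || n_steps < 1) stop("n_steps must be positive")
  stopifnot(dim %in% c(2, 3), D >= 0, n_tracks >= 1)
  set.seed(seed)
  sigma <- sqrt(2 * D * dt)
  n_pos <- n_steps + 1L
  axes <- c("x_um", "y_um", "z_um")[seq_len(dim)]
  coords <- matrix(0, nrow = n_tracks * n_pos, ncol = dim,
                   dimnames = list(NULL, axes))
  for (ax in seq_len(dim)) {
    steps <- matrix(rnorm(n_tracks * n_steps, 0, sigma),
                    nrow = n_pos - 1L)
    pos <- apply(rbind(rep(origin, n_tracks), steps), 2L, cumsum)
    coords[, ax] <- as.vector(pos)
  }
  out <- data.frame(track_id = rep(seq_len(n_tracks), each = n_pos),
                    frame = rep(seq_len(n_pos), n_tracks))
  out <- cbind(out, as.data.frame(coords))
  attr(out, "ground_truth") <- list(D = D, dt = dt)
  out
}

## Gaussian detection profile, normalized to 1 at the focus center.
.detection_weight <- function(x, y, z, w0, s) {
  w <- exp(-2 * (x^2 + y^2) / w0^2)
  if (!is.null(z)) w <- w * exp(-2 * z^2 / (s * w0)^2)
  w
}

#' Simulate a two-channel photon-count trace from diffusing species
#'
#' Particles perform periodic-boundary Brownian motion in a box of
#' `box_factor * w0` per axis around a 3D Gaussian detection volume; per-bin
#' photon counts are Poisson with mean
#' sum(brightness x exp(-2x^2/w0^2 - 2y^2/w0^2 - 2z^2/(s w0)^2)) x bin_dt.
#' Dual-labeled species emit in both channels from the same particle and so
#' produce cross-correlation; independent single-labeled species do not.
#'
#' @param species list of [species_spec()]s (non-empty).
#' @param volume a [detection_volume()].
#' @param duration trace duration, seconds.
#' @param bin_dt bin width, seconds.
#' @param box_factor box side length in units of `w0` (default 10); the box
#'   must be much larger than the detection volume.
#' @param background per-channel background rate, photons per second.
#' @param seed integer seed.
#' @param shot_noise apply Poisson statistics (default TRUE; FALSE returns
#'   the expected intensity).
#' @return an [intensity_trace()] with channels `green`, `red` and attribute
#'   `ground_truth` (per-species particle numbers and parameters).
#' @export
simulate_fcs_trace <- function(species, volume, duration, bin_dt,
                               box_factor = 10, background = c(0, 0),
                               seed = 1L, shot_noise = TRUE) {
  if (!is.list(species) || length(species) == 0L)
    stop("species list must be non-empty")
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(inherits(volume, "detection_volume"), duration > 0, bin_dt > 0,
            box_factor >= 4)
  set.seed(seed)
  n_bins <- round(duration / bin_dt)
  L <- box_factor * volume$w0
  half <- L / 2
  rate_g <- rep(background[1], n_bins)
  rate_r <- rep(background[2], n_bins)
  truth <- list()
  for (k in seq_along(species)) {
    sp <- species[[k]]
    stopifnot(inherits(sp, "species_spec"))
    n_p <- max(1L, round(sp$concentration * L^3))
    sigma <- sqrt(2 * sp$D * bin_dt)
    for (p in seq_len(n_p)) {
      x <- cumsum(c(runif(1, -half, half), rnorm(n_bins - 1L, 0, sigma)))
      y <- cumsum(c(runif(1, -half, half), rnorm(n_bins - 1L, 0, sigma)))
      z <- cumsum(c(runif(1, -half, half), rnorm(n_bins - 1L, 0, sigma)))
      ## periodic wrap into [-half, half)
      x <- (x + half) %% L - half
      y <- (y + half) %% L - half
      z <- (z + half) %% L - half
      w <- .detection_weight(x, y, z, volume$w0, volume$s)
      if (sp$brightness_g > 0) rate_g <- rate_g + sp$brightness_g * w
      if (sp$brightness_r > 0) rate_r <- rate_r + sp$brightness_r * w
    }
    truth[[k]] <- list(species = sp, n_particles = n_p)
  }
  mu_g <- rate_g * bin_dt
  mu_r <- rate_r * bin_dt
  vals <- if (shot_noise) {
    cbind(green = rpois(n_bins, mu_g), red = rpois(n_bins, mu_r))
  } else cbind(green = mu_g, red = mu_r)
  tr <- intensity_trace(vals, bin_dt)
  attr(tr, "ground_truth") <- truth
  tr
}

#' Default quasi-logarithmic lag grid for simulated correlation curves
#'
#' @param bin_dt base lag spacing, seconds.
#' @param max_lag largest lag, seconds.
#' @param m unit-spaced channels per doubling block.
#' @export
fcs_lag_grid <- function(bin_dt = 2e-5, max_lag = 1, m = 16L) {
  .multitau_lags(Inf, m, floor(max_lag / bin_dt)) * bin_dt
}

#' Simulate replicate FCCS curve triplets from model parameters
#'
#' Fast test path: evaluates the two-component model on a lag grid and adds
#' heteroscedastic Gaussian noise, emulating the replicate-to-replicate
#' scatter of measured correlation curves.  The default noise SD is
#' `noise_rel x |G_model(tau)| + noise_floor x G(0)` per curve, the scale of
#' replicate scatter in typical in-cell measurements with >= 1e7 photons.
#'
#' @param params an [fccs_params()] object (the generating truth).
#' @param volume a [detection_volume()].
#' @param lag lag grid in seconds (default [fcs_lag_grid()]).
#' @param n_replicates number of replicate triplets.
#' @param noise_rel,noise_floor relative and floor components of the noise
#'   SD (>= 0); set both 0 for noise-free curves.
#' @param noise_sd optional function `(tau, G_model)` returning the per-lag
#'   SD, overriding the default model.
#' @param seed integer seed.
#' @return list of `n_replicates` lists with elements `green`, `red`,
#'   `cross` ([correlation_curve()]s).  The `sd` column holds the empirical
#'   per-lag SD across replicates (NA, with a warning, when
#'   `n_replicates = 1`); attribute `generating_sd` holds the true noise SD.
#' @export
simulate_correlation_curves <- function(params, volume = detection_volume(0.25, 5),
                                        lag = fcs_lag_grid(),
                                        n_replicates = 1L,
                                        noise_rel = 0.03, noise_floor = 0.005,
                                        noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(params, "fccs_params"), n_replicates >= 1L)
  if (noise_rel < 0 || noise_floor < 0) stop("noise SD components must be >= 0")
  set.seed(seed)
  which_all <- c("green", "red", "cross")
  model <- lapply(setNames(which_all, which_all), function(w)
    eval_fccs_model(lag, params, w, volume))
  sds <- lapply(which_all, function(w) {
    if (is.null(noise_sd)) noise_rel * abs(model[[w]]) + noise_floor * model[[w]][1]
    else {
      s <- noise_sd(lag, model[[w]])
      if (any(s < 0)) stop("noise SD must be >= 0")
      rep_len(s, length(lag))
    }
  })
  names(sds) <- which_all
  reps <- lapply(seq_len(n_replicates), function(i) {
    lapply(setNames(which_all, which_all), function(w)
      model[[w]] + rnorm(length(lag), 0, sds[[w]]))
  })
  ## empirical per-lag SD across replicates
  emp_sd <- lapply(setNames(which_all, which_all), function(w) {
    if (n_replicates == 1L) rep(NA_real_, length(lag))
    else apply(sapply(reps, `[[`, w), 1L, sd)
  })
  if (n_replicates == 1L)
    warning("single replicate: empirical per-lag SD undefined")
  pair_of <- c(green = "green-green", red = "red-red", cross = "green-red")
  out <- lapply(reps, function(rep_i) {
    lapply(setNames(which_all, which_all), function(w) {
      cv <- correlation_curve(lag, rep_i[[w]], sd = emp_sd[[w]],
                              pair = pair_of[[w]])
      attr(cv, "generating_sd") <- sds[[w]]
      cv
    })
  })
  attr(out, "ground_truth") <- params
  out
}

## Place n points on a jittered grid with pairwise separation >= min_sep.
.place_spots <- function(n, nx, ny, min_sep, margin) {
  usable_x <- nx - 2 * margin
  usable_y <- ny - 2 * margin
  ncol_g <- floor(usable_x / min_sep)
  nrow_g <- floor(usable_y / min_sep)
  if (ncol_g * nrow_g < n)
    stop("spot density too high for requested minimum separation")
  idx <- sample(ncol_g * nrow_g, n)
  gx <- (idx - 1L) %% ncol_g
  gy <- (idx - 1L) %/% ncol_g
  jit <- (min_sep - 4) / 2
  cbind(x = margin + gx * min_sep + min_sep / 2 +
          if (jit > 0) runif(n, -jit, jit) else 0,
        y = margin + gy * min_sep + min_sep / 2 +
          if (jit > 0) runif(n, -jit, jit) else 0)
}

## Render a Gaussian spot (amplitude at peak pixel ~ amp) into an image.
.render_spot <- function(img, x, y, amp, sigma, halfwin = 5L) {
  nx <- nrow(img); ny <- ncol(img)
  i0 <- max(1L, round(x) - halfwin); i1 <- min(nx, round(x) + halfwin)
  j0 <- max(1L, round(y) - halfwin); j1 <- min(ny, round(y) + halfwin)
  ii <- i0:i1; jj <- j0:j1
  gx <- exp(-((ii - x)^2) / (2 * sigma^2))
  gy <- exp(-((jj - y)^2) / (2 * sigma^2))
  img[ii, jj] <- img[ii, jj] + amp * outer(gx, gy)
  img
}

#' Simulate a two-channel TIRF fusion-event movie
#'
#' Each event renders a diffraction-limited Gaussian spot.  The green
#' (subunit) trace steps up at arrival, persists (with optional stepwise
#' photobleaching), and steps down at departure; the red (pH-sensor) channel
#' emits a flash at the fusion time with an instantaneous rise and an
#' exponential decay over ~3 frames.  Camera noise is Poisson shot noise
#' plus Gaussian read noise per the [sim_config()].
#'
#' @param n_events number of fusion events.
#' @param arrival_offset,departure_offset functions `n -> offsets` (seconds
#'   relative to fusion; arrivals should be negative).  Defaults draw from
#'   Normal(-14.6, 4) truncated below -2 s, and Normal(1.4, 0.7).
#' @param copy_number function `n -> integer copies` per event spot.
#' @param unit_intensity peak amplitude per molecule, ADU.
#' @param flash_amplitude,flash_decay_frames red-flash peak amplitude and
#'   exponential decay constant in frames.
#' @param bleach_rate per-molecule bleaching probability per frame (0
#'   disables bleaching).
#' @param duration movie duration, seconds.
#' @param img_size image size in pixels `c(nx, ny)`; enlarged automatically
#'   if too small for `n_events` at `min_separation_px`.
#' @param min_separation_px minimum pairwise spot separation, pixels.
#' @param background constant background level, ADU.
#' @param config a [sim_config()] (frame rate, PSF, noise, seed).
#' @return object of class `tirf_movie`: list with `green` and `red` frame
#'   arrays `[x, y, frame]`, `config`, `frame_times` (frame-center times,
#'   s), and `ground_truth` data.frame
#'   `{event, x_px, y_px, t_fusion, t_arrival, t_departure, copies}`
#'   (absolute seconds).
#' @export
simulate_tirf_movie <- function(n_events,
                                arrival_offset = function(n) pmin(rnorm(n, -14.6, 4), -2),
                                departure_offset = function(n) rnorm(n, 1.4, 0.7),
                                copy_number = function(n) rep(2L, n),
                                unit_intensity = 50,
                                flash_amplitude = 300,
                                flash_decay_frames = 3,
                                bleach_rate = 0,
                                duration = 60,
                                img_size = NULL,
                                min_separation_px = 8,
                                background = 10,
                                config = sim_config()) {
  stopifnot(n_events >= 1L, duration > 0, min_separation_px >= 4)
  set.seed(config$seed)
  n_frames <- round(duration / config$frame_dt)
  frame_times <- (seq_len(n_frames) - 0.5) * config$frame_dt
  if (is.null(img_size)) {
    side <- ceiling(sqrt(n_events)) * min_separation_px + 2 * min_separation_px
    img_size <- c(side, side)
  }
  margin <- min_separation_px
  pos <- .place_spots(n_events, img_size[1], img_size[2],
                      min_separation_px, margin)
  arr <- arrival_offset(n_events)
  dep <- departure_offset(n_events)
  if (any(dep <= arr)) stop("departure offsets must exceed arrival offsets")
  copies <- as.integer(copy_number(n_events))
  stopifnot(all(copies >= 1L))
  ## fusion times leave room for the earliest arrival and latest departure
  lo <- max(2, -min(arr) + 1)
  hi <- duration - max(dep) - 2
  if (hi <= lo) stop("movie duration too short for the offset distributions")
  t_fus <- runif(n_events, lo, hi)
  t_arr <- t_fus + arr
  t_dep <- t_fus + dep

  ## per-event, per-frame green amplitude (molecules present x unit)
  green <- array(background, dim = c(img_size[1], img_size[2], n_frames))
  red <- array(background, dim = c(img_size[1], img_size[2], n_frames))
  for (e in seq_len(n_events)) {
    active <- which(frame_times >= t_arr[e] & frame_times <= t_dep[e])
    if (length(active) == 0L) next
    n_mol <- rep(copies[e], length(active))
    if (bleach_rate > 0 && copies[e] > 0L) {
      bleach_fr <- rgeom(copies[e], bleach_rate) + 1L     # frames survived
      n_mol <- vapply(seq_along(active), function(i)
        sum(bleach_fr >= i), numeric(1))
    }
    for (i in seq_along(active)) {
      f <- active[i]
      if (n_mol[i] > 0)
        green[, , f] <- .render_spot(green[, , f], pos[e, 1], pos[e, 2],
                                     n_mol[i] * unit_intensity,
                                     config$psf_sigma_px)
    }
    flash_frames <- which(frame_times >= t_fus[e] &
                            frame_times <= t_fus[e] + 10 * flash_decay_frames * config$frame_dt)
    for (f in flash_frames) {
      amp <- flash_amplitude *
        exp(-(frame_times[f] - t_fus[e]) / (flash_decay_frames * config$frame_dt))
      red[, , f] <- .render_spot(red[, , f], pos[e, 1], pos[e, 2],
                                 amp, config$psf_sigma_px)
    }
  }
  if (isTRUE(config$noise$photon)) {
    green[] <- rpois(length(green), pmax(green, 0))
    red[] <- rpois(length(red), pmax(red, 0))
  }
  if (config$noise$read_sd > 0) {
    green[] <- green + rnorm(length(green), 0, config$noise$read_sd)
    red[] <- red + rnorm(length(red), 0, config$noise$read_sd)
  }
  structure(list(
    green = green, red = red, config = config, frame_times = frame_times,
    background = background,
    ground_truth = data.frame(event = seq_len(n_events),
                              x_px = pos[, 1], y_px = pos[, 2],
                              t_fusion = t_fus, t_arrival = t_arr,
                              t_departure = t_dep, copies = copies)),
    class = "tirf_movie")
}

#' Simulate stepwise photobleaching intensity traces
#'
#' Each trace starts at the summed intensity of `copies` fluorophores whose
#' per-molecule unit intensities have coefficient of variation `cv`; each
#' molecule bleaches at a random frame (uniform over the middle of the
#' trace), producing a descending staircase, plus Gaussian camera noise.
#'
#' @param n_traces number of traces.
#' @param copies fluorophore copies per trace (recycled).
#' @param unit_intensity mean per-molecule intensity, ADU.
#' @param cv per-molecule intensity coefficient of variation.
#' @param n_frames trace length in frames.
#' @param noise_sd additive Gaussian noise SD, ADU.
#' @param seed integer seed.
#' @return list with `traces` (list of numeric vectors) and `truth`
#'   (data.frame `{trace, copies, I0}` plus list-column-free step records in
#'   attribute `steps`: list of per-trace bleach frames).
#' @export
simulate_bleach_traces <- function(n_traces, copies, unit_intensity = 100,
                                   cv = 0.3, n_frames = 200, noise_sd = 20,
                                   seed = 1L) {
  stopifnot(n_traces >= 1, all(copies >= 1), n_frames >= 20)
  set.seed(seed)
  copies <- rep_len(as.integer(copies), n_traces)
  traces <- vector("list", n_traces)
  steps <- vector("list", n_traces)
  I0 <- numeric(n_traces)
  for (i in seq_len(n_traces)) {
    k <- copies[i]
    units <- pmax(rnorm(k, unit_intensity, cv * unit_intensity),
                  0.1 * unit_intensity)
    bleach <- sort(sample(seq(floor(0.15 * n_frames), floor(0.9 * n_frames)), k))
    level <- vapply(seq_len(n_frames), function(f)
      sum(units[bleach >= f]), numeric(1))
    traces[[i]] <- level + rnorm(n_frames, 0, noise_sd)
    steps[[i]] <- bleach
    I0[i] <- sum(units)
  }
  truth <- data.frame(trace = seq_len(n_traces), copies = copies, I0 = I0)
  attr(truth, "steps") <- steps
  list(traces = traces, truth = truth)
}

#' Simulate a two-color single-particle field
#'
#' Emulates a cell-lysate spread imaged in two channels: each particle
#' carries a green-tagged reporter subunit (visible with probability
#' `heterozygous_fraction`, the tagged-allele share) and is bound to a
#' red-taggable partner with probability `bound_fraction`; the red dye is
#' visible on a bound partner with probability `labeling_fraction`
#' (Bernoulli dye labeling).  Unpaired red spots occur at `chance_density`
#' per square micrometre, producing chance colocalization.
#'
#' @param n number of reporter particles.
#' @param bound_fraction,labeling_fraction,heterozygous_fraction
#'   probabilities in `[0, 1]`.
#' @param chance_density unpaired red spots per square micrometre.
#' @param field_px field size in pixels `c(nx, ny)`.
#' @param pixel_size micrometres per pixel.
#' @param jitter_px localization jitter between channels, pixels (SD).
#' @param seed integer seed.
#' @return list with `green` and `red` spot tables (data.frames
#'   `{frame, channel, x_px, y_px, intensity}`) and `truth` (per-particle
#'   data.frame `{bound, green_visible, red_visible}` plus counts).
#' @export
simulate_two_color_particles <- function(n, bound_fraction, labeling_fraction,
                                         chance_density = 0,
                                         heterozygous_fraction = 1,
                                         field_px = c(256, 256),
                                         pixel_size = 0.12,
                                         jitter_px = 0.3, seed = 1L) {
  for (p in c(bound_fraction, labeling_fraction, heterozygous_fraction))
    if (p < 0 || p > 1) stop("fractions must lie in [0, 1]")
  stopifnot(n >= 1, chance_density >= 0)
  set.seed(seed)
  x <- runif(n, 1, field_px[1] - 1)
  y <- runif(n, 1, field_px[2] - 1)
  bound <- rbinom(n, 1, bound_fraction) == 1L
  green_vis <- rbinom(n, 1, heterozygous_fraction) == 1L
  red_vis <- bound & (rbinom(n, 1, labeling_fraction) == 1L)
  green <- data.frame(frame = 1L, channel = "green",
                      x_px = x[green_vis], y_px = y[green_vis],
                      intensity = 1)
  rx <- x[red_vis] + rnorm(sum(red_vis), 0, jitter_px)
  ry <- y[red_vis] + rnorm(sum(red_vis), 0, jitter_px)
  area_um2 <- prod(field_px) * pixel_size^2
  n_chance <- rpois(1, chance_density * area_um2)
  if (n_chance > 0) {
    rx <- c(rx, runif(n_chance, 1, field_px[1] - 1))
    ry <- c(ry, runif(n_chance, 1, field_px[2] - 1))
  }
  red <- data.frame(frame = rep(1L, length(rx)),
                    channel = rep("red", length(rx)),
                    x_px = rx, y_px = ry,
                    intensity = rep(1, length(rx)))
  truth <- data.frame(bound = bound, green_visible = green_vis,
                      red_visible = red_vis)
  list(green = green, red = red, truth = truth,
       n_chance = n_chance, field_px = field_px, pixel_size = pixel_size)
}
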