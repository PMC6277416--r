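#' Confocal detection volume geometry
#'
#' The detection volume is approximated as a 3D Gaussian with lateral 1/e^2
#' radius `w0` and axial aspect ratio `s` (axial radius = `s * w0`).
#'
#' @param w0 lateral 1/e^2 radius in micrometres.
#' @param s dimensionless axial aspect ratio; must exceed 1 for a 3D volume,
#'   `NA` for a purely 2D (membrane) geometry.
#' @export
detection_volume <- function(w0, s = 5) {
  stopifnot(is.numeric(w0), length(w0) == 1L, w0 > 0)
  if (!is.na(s) && s <= 1) stop("aspect ratio s must be > 1 for a 3D volume")
  structure(list(w0 = w0, s = s), class = "detection_volume")
}

#' Physical constants for Stokes-Einstein conversion
#'
#' @param T_K temperature in kelvin (default 293.15 K = 20 degrees C, the
#'   measurement temperature).
#' @param eta_Pa_s solvent viscosity in pascal-seconds (default 1.002e-3,
#'   water at 20 degrees C).
#' @export
physical_constants <- function(T_K = 293.15, eta_Pa_s = 1.002e-3) {
  stopifnot(T_K > 0, eta_Pa_s > 0)
  list(k_B = 1.380649e-23, T_K = T_K, eta_Pa_s = eta_Pa_s)
}

#' Single-species diffusion terms of the correlation model
#'
#' `diff_term_3d` is the normalized correlation decay of one species
#' diffusing through a 3D Gaussian volume,
#' (1 + tau/tau_D)^-1 (1 + tau/(s^2 tau_D))^-1/2; `diff_term_2d` drops the
#' axial factor for membrane (2D) diffusion.
#'
#' @param tau lag time(s), seconds, >= 0.
#' @param tau_D residence (diffusion) time in the detection area, seconds.
#' @param s axial aspect ratio of the detection volume.
#' @export
diff_term_3d <- function(tau, tau_D, s) {
  if (!is.numeric(tau_D) || tau_D <= 0) stop("tau_D must be positive")
  stopifnot(all(tau >= 0), s > 0)
  (1 + tau / tau_D)^-1 * (1 + tau / (s^2 * tau_D))^-0.5
}

#' @rdname diff_term_3d
#' @export
diff_term_2d <- function(tau, tau_D) {
  if (!is.numeric(tau_D) || tau_D <= 0) stop("tau_D must be positive")
  stopifnot(all(tau >= 0))
  (1 + tau / tau_D)^-1
}

#' Two-component FCCS model parameters
#'
#' The autocorrelation of each channel is a two-component mixture
#' G_j(tau) = G_j(0) (f_D1 Diff_D1j(tau) + f_D2 Diff_D2(tau)), j = green or
#' red, while the cross-correlation carries only the slow co-diffusing
#' component, G_x(tau) = G_x(0) Diff_D2(tau), whose residence time tau_D2 is
#' shared with the slow component of both autocorrelations.  For singly
#' labeled proteins f_D1 and f_D2 (= 1 - f_D1) are mole fractions of the
#' fast and slow species.
#'
#' @param G_g0,G_r0,G_x0 zero-lag amplitudes of the green auto, red auto and
#'   cross curves (>= 0).
#' @param f_D2 slow-component fraction in `[0, 1]`; `f_D1 = 1 - f_D2`.
#' @param tau_D1g,tau_D1r fast-component residence times (s) in the green
#'   and red channels.
#' @param tau_D2 shared slow-component residence time (s).
#' @param dimensionality `"3d"` (cytosol) or `"2d"` (membrane).
#' @export
fccs_params <- function(G_g0, G_r0, G_x0, f_D2, tau_D1g, tau_D1r, tau_D2,
                        dimensionality = c("3d", "2d")) {
  dimensionality <- match.arg(dimensionality)
  stopifnot(G_g0 >= 0, G_r0 >= 0, G_x0 >= 0,
            f_D2 >= 0, f_D2 <= 1,
            tau_D1g > 0, tau_D1r > 0, tau_D2 > 0)
  structure(list(G_g0 = G_g0, G_r0 = G_r0, G_x0 = G_x0,
                 f_D1 = 1 - f_D2, f_D2 = f_D2,
                 tau_D1g = tau_D1g, tau_D1r = tau_D1r, tau_D2 = tau_D2,
                 dimensionality = dimensionality),
            class = "fccs_params")
}

#' Evaluate the two-component FCCS model
#'
#' @param tau lag times, seconds.
#' @param params an [fccs_params()] object.
#' @param which `"green"`, `"red"` (two-component autocorrelations) or
#'   `"cross"` (slow component only).
#' @param volume a [detection_volume()] supplying the aspect ratio for the
#'   3D diffusion terms (ignored for 2D).
#' @return numeric G(tau).
#' @export
eval_fccs_model <- function(tau, params, which = c("green", "red", "cross"),
                            volume = detection_volume(0.25, 5)) {
  which <- match.arg(which)
  stopifnot(inherits(params, "fccs_params"))
  dterm <- if (params$dimensionality == "3d") {
    function(tau, tau_D) diff_term_3d(tau, tau_D, volume$s)
  } else {
    function(tau, tau_D) diff_term_2d(tau, tau_D)
  }
  slow <- dterm(tau, params$tau_D2)
  switch(which,
    green = params$G_g0 * (params$f_D1 * dterm(tau, params$tau_D1g) +
                             params$f_D2 * slow),
    red   = params$G_r0 * (params$f_D1 * dterm(tau, params$tau_D1r) +
                             params$f_D2 * slow),
    cross = params$G_x0 * slow)
}

#' Diffusion coefficient from residence time
#'
#' D = w0^2 / (4 tau_D), in micrometres squared per second.
#'
#' @param tau_D residence time, s (> 0).
#' @param w0 lateral 1/e^2 radius of the detection volume, micrometres (> 0).
#' @export
diffusion_from_tau <- function(tau_D, w0) {
  stopifnot(all(tau_D > 0), w0 > 0)
  w0^2 / (4 * tau_D)
}

#' Hydrodynamic radius via Stokes-Einstein
#'
#' R_H = k_B T / (6 pi eta D), returned in nanometres.
#'
#' @param D diffusion coefficient in micrometres squared per second (> 0).
#' @param constants a [physical_constants()] list.
#' @export
hydrodynamic_radius <- function(D, constants = physical_constants()) {
  if (any(D <= 0)) stop("D must be positive")
  D_SI <- D * 1e-12                       # um^2/s -> m^2/s
  R_m <- constants$k_B * constants$T_K / (6 * pi * constants$eta_Pa_s * D_SI)
  R_m * 1e9                               # m -> nm
}

#' Coupling fractions from correlation amplitudes
#'
#' fraction of green bound = G_x(0)/G_r(0); fraction of red bound =
#' G_x(0)/G_g(0).  Values outside `[0, 1]` are clipped with a warning (they
#' arise only from noise).
#'
#' @param G_g0,G_r0,G_x0 zero-lag amplitudes; auto amplitudes must be > 0.
#' @return named numeric vector `c(green = ..., red = ...)`.
#' @export
coupling_fractions <- function(G_g0, G_r0, G_x0) {
  stopifnot(G_g0 > 0, G_r0 > 0, G_x0 >= 0)
  fr <- c(green = G_x0 / G_r0, red = G_x0 / G_g0)
  if (any(fr > 1)) {
    warning("coupling fraction exceeded 1; clipped")
    fr <- pmin(fr, 1)
  }
  fr
}

#' Spectral cross-talk correction of FCCS amplitudes
#'
#' Removes the false cross-correlation produced by green-fluorophore signal
#' bleeding into the red detection channel.  Under a linear bleedthrough
#' model (observed red = true red + kappa x green) the true cross covariance
#' and red variance are recovered exactly from the observed amplitudes and
#' mean intensities, and corrected coupling fractions are recomputed from
#' the corrected amplitudes.
#'
#' @param G_g0,G_r0,G_x0 observed zero-lag amplitudes.
#' @param I_green,I_red mean intensities of the green and (observed) red
#'   channels, same units.
#' @param bleedthrough kappa in `[0, 1)`: fraction of green intensity
#'   registered in the red channel.
#' @return list with `amplitudes` (corrected `G_g0`, `G_r0`, `G_x0`),
#'   `fractions` (corrected coupling fractions) and
#'   `correction` (absolute change in each fraction).
#' @export
crosstalk_correction <- function(G_g0, G_r0, G_x0, I_green, I_red,
                                 bleedthrough) {
  if (bleedthrough < 0 || bleedthrough >= 1)
    stop("bleedthrough coefficient must be in [0, 1)")
  stopifnot(I_green > 0, I_red > 0)
  raw <- coupling_fractions(G_g0, G_r0, G_x0)
  k <- bleedthrough
  I_r_true <- I_red - k * I_green
  if (I_r_true <= 0) stop("bleedthrough exceeds observed red intensity")
  cov_gr <- G_x0 * I_green * I_red - k * G_g0 * I_green^2
  var_r  <- G_r0 * I_red^2 - 2 * k * cov_gr - k^2 * G_g0 * I_green^2
  cov_gr <- max(cov_gr, 0)
  var_r  <- max(var_r, .Machine$double.eps * G_r0 * I_red^2)
  G_x0_c <- cov_gr / (I_green * I_r_true)
  G_r0_c <- var_r / I_r_true^2
  corrected <- coupling_fractions(G_g0, G_r0_c, G_x0_c)
  list(amplitudes = c(G_g0 = G_g0, G_r0 = G_r0_c, G_x0 = G_x0_c),
       fractions = corrected,
       correction = corrected - raw)
}

## Stacked weighted residuals for the joint three-curve fit.
.fccs_residuals <- function(theta, curves, sds, volume, dimensionality) {
  p <- fccs_params(G_g0 = theta[["G_g0"]], G_r0 = theta[["G_r0"]],
                   G_x0 = theta[["G_x0"]], f_D2 = theta[["f_D2"]],
                   tau_D1g = exp(theta[["ltau_D1g"]]),
                   tau_D1r = exp(theta[["ltau_D1r"]]),
                   tau_D2 = exp(theta[["ltau_D2"]]),
                   dimensionality = dimensionality)
  unlist(lapply(c("green", "red", "cross"), function(w) {
    cv <- curves[[w]]
    (cv$G - eval_fccs_model(cv$lag, p, w, volume)) / sds[[w]]
  }), use.names = FALSE)
}

#' Joint fit of the two-component FCCS model to a curve triplet
#'
#' Fits the green autocorrelation, red autocorrelation and cross-correlation
#' simultaneously by weighted Levenberg-Marquardt least squares
#' (`minpack.lm`), with the slow residence time `tau_D2` shared between the
#' cross curve and the slow component of both autocorrelations, as the model
#' requires.  Each point is weighted by the per-lag standard deviation from
#' replicate measurements; if no SDs are available, uniform weights are used
#' and a message emitted.
#'
#' Initialization seeds `tau_D2` from a log-spaced grid (1e-4 to 1 s by
#' default), keeping the grid point with the lowest chi-square before
#' refinement; `f_D2` starts at 0.5.
#'
#' @param curve_g,curve_r,curve_x [correlation_curve()]s for green auto,
#'   red auto and cross.
#' @param volume a [detection_volume()]; `w0` converts residence times to
#'   diffusion coefficients, `s` enters the 3D model and is held fixed
#'   (calibrated separately), the common FCCS practice.
#' @param dimensionality `"3d"` or `"2d"`.
#' @param init optional named list overriding initial values
#'   (`G_g0, G_r0, G_x0, f_D2, tau_D1g, tau_D1r, tau_D2`).
#' @param tau_grid log-spaced candidate grid for the `tau_D2` seed.
#' @param constants [physical_constants()] for hydrodynamic radii.
#' @param maxiter maximum LM iterations.
#' @return an object of class `fccs_fit`: the fitted [fccs_params()], the
#'   derived diffusion coefficients (`D1g`, `D1r`, `D2`, micrometres squared
#'   per second), hydrodynamic radii (`R_H_fast` from the mean fast D,
#'   `R_H_slow`, nm), coupling fractions, `chisq`, degrees of freedom, and
#'   approximate standard errors from the LM covariance.
#' @export
fit_fccs <- function(curve_g, curve_r, curve_x,
                     volume = detection_volume(0.25, 5),
                     dimensionality = c("3d", "2d"),
                     init = NULL,
                     tau_grid = 10^seq(-4, 0, length.out = 17),
                     constants = physical_constants(),
                     maxiter = 200) {
  dimensionality <- match.arg(dimensionality)
  curves <- list(green = curve_g, red = curve_r, cross = curve_x)
  for (cv in curves) stopifnot(inherits(cv, "correlation_curve"))
  sds <- lapply(curves, function(cv) {
    s <- cv$sd
    if (all(is.na(s)) || all(s == 0, na.rm = TRUE)) rep(1, length(s))
    else {
      s[is.na(s) | s <= 0] <- min(s[!is.na(s) & s > 0])
      s
    }
  })
  if (all(vapply(curves, function(cv) all(is.na(cv$sd)), logical(1))))
    message("no per-lag SDs available; using uniform weights")

  amp0 <- vapply(curves, function(cv) max(cv$G[1], 1e-6), numeric(1))
  start <- list(G_g0 = amp0[["green"]], G_r0 = amp0[["red"]],
                G_x0 = amp0[["cross"]], f_D2 = 0.5,
                tau_D1g = NA, tau_D1r = NA, tau_D2 = NA)
  ## grid-seed tau_D2 (and tau_D1 = tau_D2/20) by chi-square
  best <- NULL
  for (td2 in tau_grid) {
    th <- c(G_g0 = start$G_g0, G_r0 = start$G_r0, G_x0 = start$G_x0,
            f_D2 = 0.5, ltau_D1g = log(td2 / 20), ltau_D1r = log(td2 / 20),
            ltau_D2 = log(td2))
    cs <- sum(.fccs_residuals(th, curves, sds, volume, dimensionality)^2)
    if (is.null(best) || cs < best$cs) best <- list(th = th, cs = cs)
  }
  start$tau_D2 <- exp(best$th[["ltau_D2"]])
  start$tau_D1g <- start$tau_D1r <- start$tau_D2 / 20
  if (!is.null(init)) start[names(init)] <- init

  theta0 <- c(G_g0 = start$G_g0, G_r0 = start$G_r0, G_x0 = start$G_x0,
              f_D2 = start$f_D2,
              ltau_D1g = log(start$tau_D1g), ltau_D1r = log(start$tau_D1r),
              ltau_D2 = log(start$tau_D2))
  lower <- c(0, 0, 0, 0, log(1e-7), log(1e-7), log(1e-7))
  upper <- c(Inf, Inf, Inf, 1, log(1e3), log(1e3), log(1e3))
  fit <- minpack.lm::nls.lm(
    par = theta0, lower = lower, upper = upper,
    fn = .fccs_residuals, curves = curves, sds = sds,
    volume = volume, dimensionality = dimensionality,
    control = minpack.lm::nls.lm.control(maxiter = maxiter))
  if (fit$info == 0 || fit$info == 9)
    stop("FCCS fit did not converge after ", maxiter,
         " iterations (last chi-square ", signif(fit$deviance, 6), ")")
  th <- fit$par
  pars <- fccs_params(G_g0 = th[["G_g0"]], G_r0 = th[["G_r0"]],
                      G_x0 = th[["G_x0"]], f_D2 = th[["f_D2"]],
                      tau_D1g = exp(th[["ltau_D1g"]]),
                      tau_D1r = exp(th[["ltau_D1r"]]),
                      tau_D2 = exp(th[["ltau_D2"]]),
                      dimensionality = dimensionality)
  n_obs <- sum(vapply(curves, nrow, integer(1)))
  dof <- n_obs - length(theta0)
  se <- tryCatch({
    cv <- fit$deviance / dof * solve(fit$hessian)
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) rep(NA_real_, length(theta0)))
  names(se) <- names(theta0)
  D1g <- diffusion_from_tau(pars$tau_D1g, volume$w0)
  D1r <- diffusion_from_tau(pars$tau_D1r, volume$w0)
  D2 <- diffusion_from_tau(pars$tau_D2, volume$w0)
  fr <- suppressWarnings(
    coupling_fractions(pars$G_g0, pars$G_r0, pars$G_x0))
  structure(list(
    params = pars, volume = volume,
    D1g = D1g, D1r = D1r, D2 = D2,
    R_H_fast = hydrodynamic_radius(mean(c(D1g, D1r)), constants),
    R_H_slow = hydrodynamic_radius(D2, constants),
    fraction_green_bound = fr[["green"]],
    fraction_red_bound = fr[["red"]],
    chisq = fit$deviance, dof = dof, se = se,
    converged = TRUE, niter = fit$niter), class = "fccs_fit")
}

#' @export
print.fccs_fit <- function(x, ...) {
  p <- x$params
  cat("Two-component FCCS joint fit (", p$dimensionality, ")\n", sep = "")
  cat(sprintf("  amplitudes G_g0 = %.4g, G_r0 = %.4g, G_x0 = %.4g\n",
              p$G_g0, p$G_r0, p$G_x0))
  cat(sprintf("  f_slow = %.3f; tau_D1(g,r) = %.3g, %.3g s; tau_D2 = %.3g s\n",
              p$f_D2, p$tau_D1g, p$tau_D1r, p$tau_D2))
  cat(sprintf("  D_fast(g,r) = %.3g, %.3g; D_slow = %.3g um^2/s\n",
              x$D1g, x$D1r, x$D2))
  cat(sprintf("  R_H fast = %.3g nm, slow = %.3g nm\n",
              x$R_H_fast, x$R_H_slow))
  cat(sprintf("  bound fractions: green = %.3f, red = %.3f\n",
              x$fraction_green_bound, x$fraction_red_bound))
  cat(sprintf("  chi-square = %.4g on %d dof (%d iterations)\n",
              x$chisq, x$dof, x$niter))
  invisible(x)
}

#' Calibrate detection-volume geometry from a reference dye
#'
#' Fits a single-species model to the autocorrelation of a free dye with
#' known diffusion coefficient and inverts D = w0^2/(4 tau_D) for the
#' lateral radius.
#'
#' @param reference_curve [correlation_curve()] of the reference dye.
#' @param D_known its diffusion coefficient, micrometres squared per second.
#' @param dimensionality `"3d"` fits the aspect ratio `s`; for `"2d"` `s` is
#'   undefined and returned as `NA` with a message.
#' @param s_init initial aspect ratio.
#' @param max_rel_residual calibration is rejected when the RMS residual
#'   exceeds this fraction of the amplitude (poor fit).
#' @return a [detection_volume()] with attributes `tau_D`, `G0`, `rms_rel`.
#' @export
calibrate_volume <- function(reference_curve, D_known,
                             dimensionality = c("3d", "2d"),
                             s_init = 5, max_rel_residual = 0.05) {
  dimensionality <- match.arg(dimensionality)
  stopifnot(inherits(reference_curve, "correlation_curve"), D_known > 0)
  tau <- reference_curve$lag
  G <- reference_curve$G
  if (dimensionality == "3d") {
    resid_fn <- function(th)
      G - th[1] * diff_term_3d(tau, exp(th[2]), exp(th[3]))
    th0 <- c(max(G[1], 1e-6), log(tau[which.min(abs(G - G[1] / 2))]),
             log(s_init))
  } else {
    resid_fn <- function(th)
      G - th[1] * diff_term_2d(tau, exp(th[2]))
    th0 <- c(max(G[1], 1e-6), log(tau[which.min(abs(G - G[1] / 2))]))
  }
  fit <- minpack.lm::nls.lm(par = th0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  G0 <- fit$par[1]; tau_D <- exp(fit$par[2])
  rms_rel <- sqrt(mean(resid_fn(fit$par)^2)) / G0
  if (rms_rel > max_rel_residual)
    stop(sprintf("calibration rejected: RMS residual %.3g exceeds %.3g of amplitude",
                 rms_rel, max_rel_residual))
  s <- if (dimensionality == "3d") exp(fit$par[3]) else {
    message("2D reference: aspect ratio s undefined")
    NA_real_
  }
  w0 <- sqrt(4 * D_known * tau_D)
  vol <- detection_volume(w0, s)
  attr(vol, "tau_D") <- tau_D
  attr(vol, "G0") <- G0
  attr(vol, "rms_rel") <- rms_rel
  vol
}
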