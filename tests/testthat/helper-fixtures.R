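# Shared fixtures: the in-cell FCCS study conditions (slow co-diffusing
# complex at D = 0.54 um^2/s, fast free subunits at 14.5 um^2/s, slow mole
# fraction 0.49) in a calibrated 0.25 um / s = 5 detection volume.

default_volume <- function() detection_volume(0.25, 5)

cell_params <- function(fraction_green = 0.92, G_g0 = 0.5, G_r0 = 0.4) {
  w0 <- 0.25
  fccs_params(G_g0 = G_g0, G_r0 = G_r0, G_x0 = fraction_green * G_r0,
              f_D2 = 0.49,
              tau_D1g = w0^2 / (4 * 14.5), tau_D1r = w0^2 / (4 * 14.5),
              tau_D2 = w0^2 / (4 * 0.54))
}

# Noiseless descending staircase with k unit steps (k+1 plateaus).
staircase <- function(k, plateau = 20, unit = 100) {
  rep(seq(k, 0) * unit, each = plateau)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / abs(expected), rel_tol)
}
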