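#' Octamer / tetramer / free-subunit state abundances
#'
#' Converts pairwise coupling measurements into abundances of the three
#' assembly states of the octameric tethering complex.  The
#' SEC5 + EXO70 coupling reports cross-subcomplex (octamer) association;
#' the SEC5 + SEC8 coupling reports all SC1-containing assemblies, so the
#' SC1-tetramer abundance is their difference:
#'
#' octamer = f(SEC5 + EXO70);
#' tetramer_SC1 = f(SEC5 + SEC8) - f(SEC5 + EXO70);
#' free = 100 - octamer - tetramer; and, when the SEC3 + SEC5 coupling is
#' supplied, free_SEC3 = 100 - f(SEC3 + SEC5).
#'
#' The model presumes nested colocalization, so
#' `f_sec5_sec8 < f_sec5_exo70` (a negative tetramer abundance) is an
#' error, not a clip.
#'
#' @param f_sec5_sec8,f_sec5_exo70 pairwise coupling percentages in
#'   `[0, 100]`.
#' @param f_sec3_sec5 optional SEC3 + SEC5 coupling percentage.
#' @return object of class `state_abundances`: list with `octamer`,
#'   `tetramer_sc1`, `free`, `free_sec3` (percent; components sum to 100).
#' @export
state_abundances <- function(f_sec5_sec8, f_sec5_exo70, f_sec3_sec5 = NULL) {
  for (f in c(f_sec5_sec8, f_sec5_exo70, f_sec3_sec5))
    if (f < 0 || f > 100) stop("coupling fractions must be in [0, 100] percent")
  if (f_sec5_sec8 < f_sec5_exo70)
    stop("f(SEC5+SEC8) < f(SEC5+EXO70): negative tetramer abundance; ",
         "the nested-colocalization model does not apply to these inputs")
  octamer <- f_sec5_exo70
  tetramer <- f_sec5_sec8 - f_sec5_exo70
  free <- 100 - octamer - tetramer
  structure(list(octamer = octamer, tetramer_sc1 = tetramer, free = free,
                 free_sec3 = if (is.null(f_sec3_sec5)) NA_real_
                 else 100 - f_sec3_sec5),
            class = "state_abundances")
}

#' @export
print.state_abundances <- function(x, ...) {
  cat(sprintf("state_abundances: octamer %.1f%%, SC1 tetramer %.1f%%, free %.1f%%",
              x$octamer, x$tetramer_sc1, x$free))
  if (!is.na(x$free_sec3)) cat(sprintf(" (free SEC3 %.1f%%)", x$free_sec3))
  cat("\n")
  invisible(x)
}

#' Measurement presets for the state-abundance model
#'
#' Two input sets ship: `"cytosol_fccs"` (FCCS coupling fractions measured
#' in the cytosol: SEC5+SEC8 92%, SEC5+EXO70 64%, SEC3+SEC5 67%) and
#' `"membrane_tirf"` (TIRF coincidence at the membrane: 85%, 60%, 60%).
#'
#' @param preset preset name.
#' @return list of input percentages suitable for
#'   `do.call(state_abundances, ...)`.
#' @export
state_preset <- function(preset = c("membrane_tirf", "cytosol_fccs")) {
  preset <- match.arg(preset)
  switch(preset,
    membrane_tirf = list(f_sec5_sec8 = 85, f_sec5_exo70 = 60,
                         f_sec3_sec5 = 60),
    cytosol_fccs = list(f_sec5_sec8 = 92, f_sec5_exo70 = 64,
                        f_sec3_sec5 = 67))
}

#' Monte-Carlo uncertainty propagation through the state model
#'
#' Draws the input couplings from independent normal distributions
#' (mean, SEM), maps each draw through [state_abundances()], and reports
#' percentile confidence intervals.  Draws violating the nested ordering
#' are dropped and counted.
#'
#' @param means named list/vector with `f_sec5_sec8`, `f_sec5_exo70` and
#'   optionally `f_sec3_sec5` (percent).
#' @param sems standard errors of the same inputs (>= 0).
#' @param n_draws Monte-Carlo draws (default 1e4).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `point` (the [state_abundances()] at the means),
#'   `mc_mean`, `ci` (matrix with `lo`/`hi` per component) and
#'   `n_dropped`.
#' @export
propagate_uncertainty <- function(means, sems, n_draws = 1e4, conf = 0.95,
                                  seed = 1L) {
  means <- as.list(means); sems <- as.list(sems)
  stopifnot(all(unlist(sems) >= 0))
  set.seed(seed)
  has3 <- !is.null(means$f_sec3_sec5)
  d88 <- rnorm(n_draws, means$f_sec5_sec8, sems$f_sec5_sec8)
  d70 <- rnorm(n_draws, means$f_sec5_exo70, sems$f_sec5_exo70)
  d35 <- if (has3) rnorm(n_draws, means$f_sec3_sec5, sems$f_sec3_sec5)
  ok <- d88 >= d70 & d88 >= 0 & d88 <= 100 & d70 >= 0 & d70 <= 100
  if (has3) ok <- ok & d35 >= 0 & d35 <= 100
  draws <- cbind(octamer = d70[ok],
                 tetramer_sc1 = d88[ok] - d70[ok],
                 free = 100 - d88[ok],
                 free_sec3 = if (has3) 100 - d35[ok] else NA_real_)
  alpha <- (1 - conf) / 2
  ci <- apply(draws, 2L, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  rownames(ci) <- c("lo", "hi")
  list(point = do.call(state_abundances, means),
       mc_mean = colMeans(draws),
       ci = ci,
       n_dropped = n_draws - sum(ok))
}
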