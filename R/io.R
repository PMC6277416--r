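#' Write / read an image stack as multi-page TIFF
#'
#' Integer-valued stacks round-trip losslessly: values are stored as 16-bit
#' samples scaled by `max_adu`.
#'
#' @param stack array `[x, y, frame]` of non-negative values `< max_adu`.
#' @param path file path.
#' @param max_adu full-scale value mapped to the 16-bit maximum
#'   (default 65535, i.e. raw camera counts).
#' @export
write_stack_tiff <- function(stack, path, max_adu = 65535) {
  if (length(dim(stack)) == 2L) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L, max_adu > 0)
  if (min(stack) < 0 || max(stack) > max_adu)
    stop("stack values must lie in [0, max_adu]")
  pages <- lapply(seq_len(dim(stack)[3]), function(f)
    t(stack[, , f]) / max_adu)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, max_adu = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- t(pages[[f]]) * max_adu
  round(arr)
}

#' Write / read a spot table as CSV
#'
#' Column layout `{frame, channel, x_px, y_px, intensity}`.
#' @param spots spot table data.frame.
#' @param path file path.
#' @export
write_spots_csv <- function(spots, path) {
  need <- c("frame", "channel", "x_px", "y_px", "intensity")
  stopifnot(all(need %in% names(spots)))
  write.csv(spots[, union(need, names(spots))], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "channel", "x_px", "y_px", "intensity")
  if (!all(need %in% names(df)))
    stop("malformed spot-table CSV: expected columns ",
         paste(need, collapse = ", "))
  df
}

#' Write an analysis report as JSON
#'
#' @param report named list of results (numbers, vectors, data.frames).
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' A validated configuration driving [run_pipeline()].  Parameters not
#' given fall back to the acquisition defaults (12.5 Hz, 120 nm pixels,
#' 0.27-0.35 um spot diameters).
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("fccs", "events", "state")`.
#' @param seed integer seed used by every stochastic stage.
#' @param fccs list of FCCS-stage parameters: `params` ([fccs_params()]),
#'   `volume` ([detection_volume()]), `n_replicates`.
#' @param events list of event-stage parameters: `n_events`, `duration`,
#'   `frame_dt`.
#' @param state list with either `preset` (see [state_preset()]) or
#'   explicit coupling fractions.
#' @param out_dir optional output directory for JSON reports.
#' @export
pipeline_config <- function(stages = c("fccs", "events", "state"),
                            seed = 1L,
                            fccs = list(), events = list(), state = list(),
                            out_dir = NULL) {
  known <- c("fccs", "events", "state")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(stages = stages, seed = as.integer(seed),
                 fccs = fccs, events = events, state = state,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the selected stages on synthetic inputs generated from the
#' configuration seed (simulate, correlate/fit, measure), collects the
#' results into a machine-readable report, and (optionally) writes it as
#' JSON.  Rerunning with the same configuration and seed reproduces the
#' report exactly.
#'
#' @param config a [pipeline_config()].
#' @return named list (one element per stage) of stage reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  if ("fccs" %in% config$stages) {
    p <- config$fccs
    params <- p$params %||% fccs_params(G_g0 = 0.5, G_r0 = 0.4,
                                        G_x0 = 0.92 * 0.4, f_D2 = 0.49,
                                        tau_D1g = 1.08e-3, tau_D1r = 1.08e-3,
                                        tau_D2 = 2.89e-2)
    volume <- p$volume %||% detection_volume(0.25, 5)
    n_rep <- p$n_replicates %||% 5L
    reps <- simulate_correlation_curves(params, volume,
                                        n_replicates = n_rep,
                                        seed = config$seed)
    fit <- fit_fccs(reps[[1]]$green, reps[[1]]$red, reps[[1]]$cross,
                    volume = volume)
    report$fccs <- list(
      fraction_green_bound = fit$fraction_green_bound,
      fraction_red_bound = fit$fraction_red_bound,
      D_slow = fit$D2, D_fast = mean(c(fit$D1g, fit$D1r)),
      R_H_fast_nm = fit$R_H_fast, R_H_slow_nm = fit$R_H_slow,
      chisq = fit$chisq)
  }
  if ("events" %in% config$stages) {
    p <- config$events
    cfg <- sim_config(seed = config$seed,
                      frame_dt = p$frame_dt %||% 0.2)
    movie <- simulate_tirf_movie(n_events = p$n_events %||% 25L,
                                 duration = p$duration %||% 60,
                                 config = cfg)
    ev <- measure_fusion_events(movie)
    sm <- summarize_events(ev[, c("t_arrival", "t_departure", "residence")],
                           seed = config$seed)
    report$events <- list(n_events = nrow(ev), summary = sm$medians)
  }
  if ("state" %in% config$stages) {
    p <- config$state
    inputs <- if (!is.null(p$preset)) state_preset(p$preset)
    else p[intersect(names(p),
                     c("f_sec5_sec8", "f_sec5_exo70", "f_sec3_sec5"))]
    if (length(inputs) < 2L)
      stop("state stage: missing coupling-fraction inputs")
    ab <- do.call(state_abundances, inputs)
    report$state <- list(inputs = inputs, abundances = unclass(ab))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}
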