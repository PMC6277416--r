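#' Mean intensity trace of a circular ROI across a frame stack
#'
#' @param stack image array `[x, y, frame]`.
#' @param x_px,y_px ROI center, pixels.
#' @param radius_px ROI radius, pixels.
#' @return numeric vector, one mean per frame.
#' @export
extract_roi_trace <- function(stack, x_px, y_px, radius_px = 3) {
  stopifnot(length(dim(stack)) == 3L, radius_px >= 1)
  nx <- dim(stack)[1]; ny <- dim(stack)[2]
  off <- -ceiling(radius_px):ceiling(radius_px)
  ii <- round(x_px) + off
  jj <- round(y_px) + off
  ok_i <- ii >= 1L & ii <= nx
  ok_j <- jj >= 1L & jj <= ny
  disk <- outer(off[ok_i]^2, off[ok_j]^2, `+`) <= radius_px^2
  sub <- stack[ii[ok_i], jj[ok_j], , drop = FALSE]
  apply(sub, 3L, function(fr) mean(fr[disk]))
}

## Runs of TRUE with length >= min_frames; returns start/end indices.
.sustained_runs <- function(above, min_frames) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  data.frame(start = starts[keep], end = ends[keep])
}

## Robust baseline/SD for traces that switch between a background level and
## an elevated "on" state.  The noise SD comes from first differences
## (insensitive to level shifts); the baseline is the median of the cluster
## within 4 SD of the lower decile, so it stays correct even when the on
## state occupies most of the trace.
.robust_baseline <- function(x) {
  sdev <- max(mad(diff(x)) / sqrt(2), 1e-12)
  base <- median(x[x <= quantile(x, 0.1, names = FALSE) + 4 * sdev])
  list(base = base, sd = sdev)
}

#' Detect vesicle-fusion flashes in a pH-sensor intensity trace
#'
#' A flash is a sustained excursion above baseline + k sigma lasting at
#' least `min_frames`; its onset is placed half a frame before the first
#' frame above threshold (midpoint convention, unbiased for an onset
#' uniform within a frame).  The baseline and noise SD are estimated
#' robustly from the lower half of the trace (flashes are sparse);
#' flashes starting within the first `baseline_frames` frames have no
#' confirmable pre-event baseline and are skipped.
#'
#' @param trace numeric ROI trace (e.g. from [extract_roi_trace()]).
#' @param frame_times frame-center times, seconds.
#' @param k_sigma threshold in baseline-noise SDs (default 3).
#' @param min_frames minimum frames above threshold (default 3).
#' @param baseline_frames flashes starting within this many initial frames
#'   are skipped (no pre-event baseline to confirm them against).
#' @return data.frame `{t_fusion, onset_frame, peak}`; zero rows when no
#'   flash qualifies.
#' @export
detect_fusion_flashes <- function(trace, frame_times, k_sigma = 3,
                                  min_frames = 3, baseline_frames = 10) {
  x <- as.numeric(trace)
  stopifnot(length(x) == length(frame_times), baseline_frames >= 3)
  frame_dt <- median(diff(frame_times))
  rb <- .robust_baseline(x)
  thr <- rb$base + k_sigma * rb$sd
  runs <- .sustained_runs(x > thr, min_frames)
  if (nrow(runs) == 0L)
    return(data.frame(t_fusion = numeric(0), onset_frame = integer(0),
                      peak = numeric(0)))
  skipped <- runs$start <= baseline_frames
  if (any(skipped))
    message(sum(skipped), " flash(es) at trace start skipped (no baseline)")
  runs <- runs[!skipped, , drop = FALSE]
  data.frame(
    t_fusion = frame_times[runs$start] - frame_dt / 2,
    onset_frame = runs$start,
    peak = vapply(seq_len(nrow(runs)), function(i)
      max(x[runs$start[i]:runs$end[i]]), numeric(1)))
}

#' Subunit arrival and departure times relative to a fusion event
#'
#' The subunit trace is thresholded at baseline + k sigma (baseline from
#' the robust lower half of the trace); the sustained above-threshold run
#' nearest the fusion time defines the event.  Arrival is placed half a
#' frame before the first frame above threshold and departure half a frame
#' after the last (midpoint convention), both reported relative to
#' `t_fusion` (negative = before fusion).
#'
#' @param trace subunit-channel ROI trace.
#' @param t_fusion fusion time, seconds (e.g. from
#'   [detect_fusion_flashes()]).
#' @param frame_times frame-center times, seconds.
#' @param k_sigma,min_frames threshold rule (defaults 3 sigma, 3 frames).
#' @return one-row data.frame `{t_arrival, t_departure, residence,
#'   right_censored}`; all `NA` (with `right_censored = NA`) when the trace
#'   never crosses threshold.
#' @export
arrival_departure <- function(trace, t_fusion, frame_times,
                              k_sigma = 3, min_frames = 3) {
  x <- as.numeric(trace)
  stopifnot(length(x) == length(frame_times))
  frame_dt <- median(diff(frame_times))
  rb <- .robust_baseline(x)
  thr <- rb$base + k_sigma * rb$sd
  runs <- .sustained_runs(x > thr, min_frames)
  if (nrow(runs) == 0L)
    return(data.frame(t_arrival = NA_real_, t_departure = NA_real_,
                      residence = NA_real_, right_censored = NA))
  mid <- (frame_times[runs$start] + frame_times[runs$end]) / 2
  r <- runs[which.min(abs(mid - t_fusion)), ]
  t_arr <- frame_times[r$start] - frame_dt / 2 - t_fusion
  t_dep <- frame_times[r$end] + frame_dt / 2 - t_fusion
  data.frame(t_arrival = t_arr, t_departure = t_dep,
             residence = t_dep - t_arr,
             right_censored = r$end == length(x))
}

#' Arrival delay between two channels of one event
#'
#' Both traces are normalized to `[0, 1]` between their robust baseline and
#' peak; each channel's arrival is the half-maximum crossing of its first
#' sustained rise, refined below the frame time by linear interpolation of
#' the crossing.  The delay is channel2 minus channel1 arrival, in
#' milliseconds; events are classed `"simultaneous"` when the absolute
#' delay is below one frame interval, `"first"` when channel 2 arrives
#' first, `"second"` when channel 2 arrives second.
#'
#' @param traceA,traceB the two channel traces (channel 1, channel 2).
#' @param frame_times frame-center times, seconds.
#' @param threshold normalized crossing level (default 0.5).
#' @param min_frames sustained-rise requirement, frames.
#' @return one-row data.frame `{delay_ms, order_class}`; `NA` delay when a
#'   channel never rises (unpaired event).
#' @export
arrival_delay <- function(traceA, traceB, frame_times, threshold = 0.5,
                          min_frames = 3) {
  frame_dt <- median(diff(frame_times))
  cross_time <- function(x) {
    rb <- .robust_baseline(x)
    peak <- quantile(x, 0.95, names = FALSE)
    if (peak <= rb$base + 3 * rb$sd) return(NA_real_)
    xn <- (x - rb$base) / (peak - rb$base)
    runs <- .sustained_runs(xn > threshold, min_frames)
    if (nrow(runs) == 0L) return(NA_real_)
    i <- runs$start[1]
    if (i == 1L) return(frame_times[1])
    ## linear interpolation of the threshold crossing between i-1 and i
    frac <- (threshold - xn[i - 1L]) / (xn[i] - xn[i - 1L])
    frame_times[i - 1L] + frac * frame_dt
  }
  tA <- cross_time(as.numeric(traceA))
  tB <- cross_time(as.numeric(traceB))
  if (is.na(tA) || is.na(tB))
    return(data.frame(delay_ms = NA_real_, order_class = NA_character_))
  delay_s <- tB - tA
  cls <- if (abs(delay_s) < frame_dt) "simultaneous"
  else if (delay_s < 0) "first" else "second"
  data.frame(delay_ms = delay_s * 1000, order_class = cls)
}

#' Summarize event statistics with bootstrap confidence intervals
#'
#' Medians with seeded percentile-bootstrap 95% CIs for every numeric
#' column, plus order-class proportions when an `order_class` column is
#' present.  Refuses to summarize fewer than 5 events.
#'
#' @param events data.frame of per-event measurements (or a numeric
#'   vector, treated as a single column `value`).
#' @param n_boot bootstrap resamples (default 1e4).
#' @param conf confidence level.
#' @param seed integer seed for the resampling.
#' @return list with `medians` (data.frame
#'   `{variable, n, median, ci_lo, ci_hi}`) and `order_class` (named
#'   proportions or `NULL`).
#' @export
summarize_events <- function(events, n_boot = 1e4, conf = 0.95, seed = 1L) {
  if (is.numeric(events)) events <- data.frame(value = events)
  events_num <- events[vapply(events, is.numeric, logical(1))]
  n <- nrow(events)
  if (n < 5L) stop("refusing to summarize fewer than 5 events")
  set.seed(seed)
  alpha <- (1 - conf) / 2
  med_rows <- lapply(names(events_num), function(v) {
    x <- events_num[[v]]
    x <- x[!is.na(x)]
    if (length(x) < 5L)
      return(data.frame(variable = v, n = length(x), median = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    boots <- vapply(seq_len(n_boot), function(i)
      median(sample(x, length(x), replace = TRUE)), numeric(1))
    data.frame(variable = v, n = length(x), median = median(x),
               ci_lo = quantile(boots, alpha, names = FALSE),
               ci_hi = quantile(boots, 1 - alpha, names = FALSE))
  })
  classes <- NULL
  if (!is.null(events$order_class)) {
    cc <- events$order_class[!is.na(events$order_class)]
    classes <- table(cc) / length(cc)
  }
  list(medians = do.call(rbind, med_rows), order_class = classes)
}

#' Run the full event-timing pipeline on a two-channel movie
#'
#' Fusion sites are located by spot detection on the maximum-intensity
#' projection of the pH-sensor (red) channel; per-site ROI traces are
#' extracted in both channels, flashes dated, and subunit arrival/departure
#' measured relative to each flash.
#'
#' @param movie a `tirf_movie` (or any list with `green`, `red`,
#'   `frame_times`, `config`).
#' @param roi_radius_px ROI radius for trace extraction.
#' @param ... passed to [arrival_departure()].
#' @return data.frame, one row per detected event:
#'   `{x_px, y_px, t_fusion, t_arrival, t_departure, residence,
#'   right_censored}`.
#' @export
measure_fusion_events <- function(movie, roi_radius_px = 3, ...) {
  proj <- apply(movie$red, c(1, 2), max)
  sites <- detect_spots(proj, pixel_size = movie$config$pixel_size)
  if (nrow(sites) == 0L) stop("no fusion sites detected in the red channel")
  rows <- lapply(seq_len(nrow(sites)), function(k) {
    red_tr <- extract_roi_trace(movie$red, sites$x_px[k], sites$y_px[k],
                                roi_radius_px)
    fl <- detect_fusion_flashes(red_tr, movie$frame_times)
    if (nrow(fl) == 0L) return(NULL)
    t_fus <- fl$t_fusion[which.max(fl$peak)]
    green_tr <- extract_roi_trace(movie$green, sites$x_px[k], sites$y_px[k],
                                  roi_radius_px)
    ad <- arrival_departure(green_tr, t_fus, movie$frame_times, ...)
    cbind(data.frame(x_px = sites$x_px[k], y_px = sites$y_px[k],
                     t_fusion = t_fus), ad)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no fusion flashes detected")
  out
}
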