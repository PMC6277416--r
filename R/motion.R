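#' Link per-frame spot detections into trajectories
#'
#' Greedy frame-to-frame mutual-nearest-neighbor linking: at each frame,
#' active track heads (tracks whose last detection is at most
#' `max_gap + 1` frames old) are matched to the new detections within
#' `max_disp`; unmatched detections seed new tracks.  Crossing particles
#' farther apart than `max_disp` are never swapped, they break.
#'
#' @param spots data.frame `{frame, x_px, y_px}` (one channel).
#' @param max_disp maximum frame-to-frame displacement, micrometres.
#' @param max_gap maximum number of missed frames to bridge (default 0).
#' @param pixel_size micrometres per pixel for the coordinate conversion.
#' @param frame_dt frame interval, seconds (stored for MSD lags).
#' @return data.frame `{track_id, frame, x_um, y_um}` with attribute
#'   `frame_dt`.
#' @export
link_tracks <- function(spots, max_disp, max_gap = 0, pixel_size = 0.12,
                        frame_dt = 0.08) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(spots)),
            max_disp > 0, max_gap >= 0)
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
  attr(empty, "frame_dt") <- frame_dt
  if (nrow(spots) == 0L) return(empty)
  spots <- spots[order(spots$frame), ]
  sx <- spots$x_px * pixel_size
  sy <- spots$y_px * pixel_size
  frames <- sort(unique(spots$frame))
  track_of <- integer(nrow(spots))
  ## active heads: track id, row index of last detection, last frame
  head_row <- integer(0)
  n_tracks <- 0L
  for (f in frames) {
    cur <- which(spots$frame == f)
    alive <- head_row[spots$frame[head_row] >= f - (max_gap + 1L)]
    if (length(alive) > 0L && length(cur) > 0L) {
      d <- sqrt(outer(sx[alive], sx[cur], `-`)^2 +
                  outer(sy[alive], sy[cur], `-`)^2)
      nnA <- apply(d, 1L, which.min)
      nnB <- apply(d, 2L, which.min)
      ia <- which(nnB[nnA] == seq_along(alive))
      ib <- nnA[ia]
      ok <- d[cbind(ia, ib)] <= max_disp
      matched_heads <- alive[ia[ok]]
      matched_cur <- cur[ib[ok]]
      track_of[matched_cur] <- track_of[matched_heads]
      head_row <- setdiff(head_row, matched_heads)
      head_row <- c(head_row, matched_cur)
      cur <- setdiff(cur, matched_cur)
    }
    if (length(cur) > 0L) {
      track_of[cur] <- n_tracks + seq_along(cur)
      n_tracks <- n_tracks + length(cur)
      head_row <- c(head_row, cur)
    }
  }
  out <- data.frame(track_id = track_of, frame = spots$frame,
                    x_um = sx, y_um = sy)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "frame_dt") <- frame_dt
  out
}

#' Time-averaged mean squared displacement of one track
#'
#' MSD(k dt) = mean over t of |r(t + k dt) - r(t)|^2.
#'
#' @param track data.frame with `x_um`, `y_um` ordered in time (single
#'   track, length >= 4).
#' @param frame_dt frame interval, seconds.
#' @param max_lag_frac largest lag as a fraction of track length.
#' @return data.frame of class `msd_curve`: `{lag_s, msd_um2, n_pairs}`.
#' @export
msd <- function(track, frame_dt = attr(track, "frame_dt") %||% 0.08,
                max_lag_frac = 0.5) {
  n <- nrow(track)
  if (n < 4L) stop("track too short for MSD (need >= 4 positions)")
  max_k <- max(1L, floor((n - 1L) * max_lag_frac))
  x <- track$x_um; y <- track$y_um
  rows <- lapply(seq_len(max_k), function(k) {
    dx <- x[(k + 1L):n] - x[1:(n - k)]
    dy <- y[(k + 1L):n] - y[1:(n - k)]
    data.frame(lag_s = k * frame_dt, msd_um2 = mean(dx^2 + dy^2),
               n_pairs = n - k)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("msd_curve", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble MSD across tracks
#'
#' Per-track time-averaged MSDs are combined per lag by the geometric mean
#' (robust to the wide per-track spread of short trajectories) or the
#' arithmetic mean; the arithmetic mean is the unbiased estimator used for
#' diffusion fitting.
#'
#' @param tracks data.frame `{track_id, frame, x_um, y_um}` from
#'   [link_tracks()] or [simulate_brownian_tracks()].
#' @param frame_dt frame interval, seconds.
#' @param average `"geometric"` or `"arithmetic"`.
#' @param min_len tracks shorter than this are skipped.
#' @return data.frame of class `msd_curve`: `{lag_s, msd_um2, n_tracks}`.
#' @export
ensemble_msd <- function(tracks, frame_dt = attr(tracks, "frame_dt") %||% 0.08,
                         average = c("geometric", "arithmetic"),
                         min_len = 4L) {
  average <- match.arg(average)
  ids <- unique(tracks$track_id)
  curves <- list()
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < min_len) next
    curves[[length(curves) + 1L]] <- msd(tr, frame_dt)
  }
  if (length(curves) == 0L) stop("no track long enough for MSD")
  all_lags <- sort(unique(unlist(lapply(curves, `[[`, "lag_s"))))
  rows <- lapply(all_lags, function(L) {
    vals <- unlist(lapply(curves, function(cv) cv$msd_um2[cv$lag_s == L]))
    m <- if (average == "geometric") {
      pos <- vals[vals > 0]
      if (length(pos) == 0L) 0 else exp(mean(log(pos)))
    } else mean(vals)
    data.frame(lag_s = L, msd_um2 = m, n_tracks = length(vals))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares fit of MSD = 4 D lag + offset over the first `n_lags`
#' lags; the free intercept absorbs static localization noise.
#'
#' @param msd_curve an [msd()] / [ensemble_msd()] result.
#' @param n_lags number of initial lags to fit (default 4; >= 3 required).
#' @return list with `D` (micrometres squared per second), `intercept_um2`,
#'   `fit`.
#' @export
fit_diffusion <- function(msd_curve, n_lags = 4L) {
  stopifnot(inherits(msd_curve, "msd_curve"))
  use <- head(msd_curve, n_lags)
  if (nrow(use) < 3L) stop("need at least 3 usable lags")
  fit <- lm(msd_um2 ~ lag_s, data = use)
  list(D = unname(coef(fit)[2L]) / 4,
       intercept_um2 = unname(coef(fit)[1L]),
       fit = fit)
}

#' Net displacement of a track
#'
#' Euclidean distance between the last and first positions, micrometres.
#' @param track data.frame with `x_um`, `y_um` (non-empty).
#' @export
total_displacement <- function(track) {
  stopifnot(nrow(track) >= 1L)
  sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
         (track$y_um[nrow(track)] - track$y_um[1])^2)
}

#' Membrane localization index
#'
#' Product of spot density and mean cell intensity (arbitrary units:
#' spots um^-2 x ADU), a simple score of how strongly a subunit populates
#' the TIRF field.
#'
#' @param spot_density spots per square micrometre (>= 0).
#' @param mean_intensity mean cell intensity, ADU (>= 0).
#' @export
membrane_localization_index <- function(spot_density, mean_intensity) {
  stopifnot(all(spot_density >= 0), all(mean_intensity >= 0))
  spot_density * mean_intensity
}
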