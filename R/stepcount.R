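#' Detect photobleaching steps by penalized change-point fitting
#'
#' Fits a piecewise-constant signal by exact least-squares optimal
#' partitioning (dynamic programming): the number and location of change
#' points minimize the total residual sum of squares plus a per-step
#' penalty.  The default penalty is `3 sigma^2 log(n)` (a BIC-like rule)
#' with the noise SD estimated robustly from the median absolute first
#' difference; this keeps the false-step rate below ~5% at signal-to-noise
#' 5 while calling true unit steps reliably.
#'
#' @param trace numeric intensity trace (>= 10 frames).
#' @param penalty per-change-point penalty; `NULL` (default) uses the
#'   BIC-like rule above.
#' @param min_plateau plateaus shorter than this trigger an
#'   unstable-count warning (degenerate traces such as monotone ramps).
#' @return object of class `step_fit`: list with `step_frames` (last frame
#'   of each plateau but the final one), `levels` (per-plateau means),
#'   `n_steps`, `residual` (RSS), `sigma_hat`, `penalty`.
#' @export
detect_steps <- function(trace, penalty = NULL, min_plateau = 3L) {
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 10L) stop("trace must contain at least 10 frames")
  sigma_hat <- mad(diff(x)) / sqrt(2)
  if (is.null(penalty)) {
    penalty <- 3 * sigma_hat^2 * log(n)
    ## strictly positive floor so exact-tie solutions prefer fewer steps
    penalty <- max(penalty, 1e-8 * diff(range(x))^2, 1e-12)
  }
  stopifnot(penalty > 0)
  S1 <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  ## rss of segment (i+1)..j given 0-based prefix index i
  seg_rss <- function(i, j) {
    len <- j - i
    (S2[j + 1L] - S2[i + 1L]) - (S1[j + 1L] - S1[i + 1L])^2 / len
  }
  F <- c(-penalty, rep(Inf, n))
  cp <- integer(n + 1L)
  for (j in seq_len(n)) {
    i <- 0:(j - 1L)
    len <- j - i
    rss <- (S2[j + 1L] - S2[i + 1L]) - (S1[j + 1L] - S1[i + 1L])^2 / len
    cand <- F[i + 1L] + rss + penalty
    k <- which.min(cand)
    F[j + 1L] <- cand[k]
    cp[j + 1L] <- i[k]
  }
  ## backtrack segment boundaries
  bounds <- integer(0)
  j <- n
  while (j > 0L) {
    i <- cp[j + 1L]
    bounds <- c(i, bounds)
    j <- i
  }
  starts <- bounds + 1L
  ends <- c(bounds[-1L], n)
  levels <- vapply(seq_along(starts), function(k)
    mean(x[starts[k]:ends[k]]), numeric(1))
  if (any(ends - starts + 1L < min_plateau))
    warning("plateau(s) shorter than ", min_plateau,
            " frames: step count may be unstable")
  structure(list(step_frames = ends[-length(ends)],
                 levels = levels,
                 n_steps = length(levels) - 1L,
                 residual = sum(vapply(seq_along(starts), function(k)
                   seg_rss(starts[k] - 1L, ends[k]), numeric(1))),
                 sigma_hat = sigma_hat, penalty = penalty),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("step_fit: %d step(s) at frame(s) %s\n", x$n_steps,
              paste(x$step_frames, collapse = ", ")))
  cat("  levels:", paste(signif(x$levels, 5), collapse = " -> "), "\n")
  invisible(x)
}

#' Initial (first-plateau) intensity of a bleaching trace
#'
#' The mean of the first plateau of the change-point fit, used as I0 for
#' the standard curve: more noise-robust than a single-frame maximum.
#'
#' @param trace numeric trace.
#' @param ... passed to [detect_steps()].
#' @export
initial_intensity <- function(trace, ...) {
  detect_steps(trace, ...)$levels[1L]
}

#' Fluorophore-count standard curve
#'
#' Ordinary least squares of initial intensity I0 against known fluorophore
#' copy number (1x, 2x, 3x tandem fusions).
#'
#' @param intensity_sets list of numeric vectors, one per copy-number class
#'   (all non-empty).
#' @param copies copy number of each class (default `seq_along`).
#' @param aggregate `"none"` regresses every trace; `"mean"` regresses the
#'   per-class means (as when calibration points are plotted as
#'   mean +/- SD).
#' @return object of class `standard_curve`: `slope` (ADU per molecule),
#'   `intercept`, `r_squared`, `points` (data.frame `{copies, I0}`), `fit`.
#' @export
build_standard_curve <- function(intensity_sets, copies = seq_along(intensity_sets),
                                 aggregate = c("none", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(intensity_sets), length(intensity_sets) == length(copies))
  if (any(vapply(intensity_sets, length, integer(1)) == 0L))
    stop("every copy-number class must be non-empty")
  if (length(unique(copies)) < 2L)
    stop("need at least two distinct copy-number classes")
  pts <- data.frame(
    copies = rep(copies, vapply(intensity_sets, length, integer(1))),
    I0 = unlist(intensity_sets, use.names = FALSE))
  if (aggregate == "mean")
    pts <- data.frame(copies = copies,
                      I0 = vapply(intensity_sets, mean, numeric(1)))
  fit <- lm(I0 ~ copies, data = pts)
  slope <- unname(coef(fit)[2L])
  if (slope <= 0) stop("standard curve slope must be positive")
  tss <- sum((pts$I0 - mean(pts$I0))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum(fit$residuals^2) / tss
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 points = pts, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: I0 = %.4g x copies + %.4g (r^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

## Gaussian-interpolated peak: exact for a noiseless Gaussian profile
## (log intensity is quadratic), falls back to the raw maximum otherwise.
.interp_peak <- function(patch) {
  im <- which(patch == max(patch), arr.ind = TRUE)[1, ]
  i <- im[1]; j <- im[2]
  if (i <= 1L || i >= nrow(patch) || j <= 1L || j >= ncol(patch))
    return(max(patch))
  vx <- patch[(i - 1L):(i + 1L), j]
  vy <- patch[i, (j - 1L):(j + 1L)]
  if (any(vx <= 0) || any(vy <= 0)) return(max(patch))
  lx <- log(vx); ly <- log(vy)
  cx <- lx[1] - 2 * lx[2] + lx[3]
  cy <- ly[1] - 2 * ly[2] + ly[3]
  if (!is.finite(cx) || !is.finite(cy) || cx >= 0 || cy >= 0)
    return(max(patch))
  peak_log <- log(patch[i, j]) - (lx[1] - lx[3])^2 / (8 * cx) -
    (ly[1] - ly[3])^2 / (8 * cy)
  exp(peak_log)
}

#' Background-subtracted peak intensities of resolved spots
#'
#' For each spot, the background (median over an annulus) is subtracted and
#' the peak of the Gaussian-interpolated spot profile is taken at its
#' brightest pre-fusion frame.  The brightest frame is selected by the
#' mean window intensity, and the measurement is taken in the frame
#' adjacent to the selected one: on the constant pre-bleach plateau the
#' expected value is identical but the noise is independent of the
#' selection, which removes the extreme-value bias of maximizing over
#' noisy frames.  Spots closer than `min_separation_px` to any other spot are
#' excluded (unresolvable within the PSF sampling criterion) with the
#' reason recorded.
#'
#' @param stack image array `[x, y, frame]` (a single matrix is treated as
#'   one frame) — e.g. the `green` element of a `tirf_movie`.
#' @param spots data.frame with columns `x_px`, `y_px` and optionally
#'   `t_fusion` (s); all spots are assumed co-resolvable in time.
#' @param min_separation_px minimum pairwise separation, pixels (default 4).
#' @param frame_times frame-center times (s), required when `t_fusion` is
#'   used to restrict to pre-fusion frames.
#' @param win half-width of the peak search window, pixels.
#' @param bg_inner,bg_outer annulus radii (pixels) for the median
#'   background.
#' @return data.frame `{spot, I0, included, reason}`; `I0` is `NA` for
#'   excluded spots.
#' @export
peak_intensity <- function(stack, spots, min_separation_px = 4,
                           frame_times = NULL, win = 2L,
                           bg_inner = 4, bg_outer = 7) {
  if (length(dim(stack)) == 2L) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L, nrow(spots) >= 1L,
            all(c("x_px", "y_px") %in% names(spots)))
  n <- nrow(spots)
  keep <- rep(TRUE, n)
  if (n > 1L) {
    d <- as.matrix(dist(spots[, c("x_px", "y_px")]))
    diag(d) <- Inf
    keep <- apply(d, 1L, min) > min_separation_px
  }
  nx <- dim(stack)[1]; ny <- dim(stack)[2]; nf <- dim(stack)[3]
  out <- data.frame(spot = seq_len(n), I0 = NA_real_,
                    included = keep,
                    reason = ifelse(keep, "",
                                    sprintf("closer than %g px to another spot",
                                            min_separation_px)))
  off <- -ceiling(bg_outer):ceiling(bg_outer)
  rr <- sqrt(outer(off^2, off^2, `+`))
  ann <- rr >= bg_inner & rr <= bg_outer
  for (k in which(keep)) {
    xi <- round(spots$x_px[k]); yi <- round(spots$y_px[k])
    frames <- seq_len(nf)
    if (!is.null(spots$t_fusion) && !is.null(frame_times))
      frames <- which(frame_times < spots$t_fusion[k])
    if (length(frames) == 0L) {
      out$included[k] <- FALSE
      out$reason[k] <- "no pre-fusion frames"
      next
    }
    i0 <- max(1L, xi - win); i1 <- min(nx, xi + win)
    j0 <- max(1L, yi - win); j1 <- min(ny, yi + win)
    bi <- pmax(1L, pmin(nx, xi + off))
    bj <- pmax(1L, pmin(ny, yi + off))
    win_mean <- vapply(frames, function(f)
      mean(stack[i0:i1, j0:j1, f]), numeric(1))
    sel <- which.max(win_mean)
    ## measure in the adjacent frame: same plateau, independent noise
    f_meas <- frames[if (sel > 1L) sel - 1L
                     else if (sel < length(frames)) sel + 1L else sel]
    bg <- median(stack[bi, bj, f_meas][ann])
    out$I0[k] <- .interp_peak(stack[i0:i1, j0:j1, f_meas] - bg)
  }
  out
}

#' Convert spot intensities to molecule counts
#'
#' copies = heterozygosity_factor x (I0 - intercept) / slope.  For cell
#' lines in which only one allele carries the tag, the factor 2 doubles the
#' raw estimate.
#'
#' @param I0 numeric peak intensities.
#' @param curve a [standard_curve()].
#' @param heterozygosity_factor 1 (homozygous tag) or 2 (heterozygous).
#' @param spot_id optional identifiers.
#' @return data.frame `{spot_id, raw, corrected}`; negative estimates are
#'   clipped to 0 with a warning.
#' @export
count_molecules <- function(I0, curve, heterozygosity_factor = 1,
                            spot_id = seq_along(I0)) {
  stopifnot(inherits(curve, "standard_curve"),
            heterozygosity_factor %in% c(1, 2))
  raw <- (I0 - curve$intercept) / curve$slope
  if (any(raw < 0, na.rm = TRUE)) {
    warning("negative molecule count(s) clipped to 0")
    raw <- pmax(raw, 0)
  }
  data.frame(spot_id = spot_id, raw = raw,
             corrected = heterozygosity_factor * raw)
}
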