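#' Two-channel intensity trace
#'
#' Container for a uniformly sampled fluorescence intensity signal with one
#' or more detection channels, the basic input of the software correlator.
#'
#' @param values numeric vector (one channel) or matrix with one column per
#'   channel; photon counts or camera ADU per time bin.
#' @param bin_dt sampling interval in seconds.
#' @param channels optional channel labels; defaults to column names or
#'   `"ch1"`, `"ch2"`, ...
#' @return an object of class `intensity_trace`: a list with elements
#'   `values` (matrix), `bin_dt`, `channels`.
#' @export
intensity_trace <- function(values, bin_dt, channels = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 2L)
  if (!is.numeric(bin_dt) || length(bin_dt) != 1L || bin_dt <= 0)
    stop("bin_dt must be a single positive number")
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  }
  stopifnot(length(channels) == ncol(values))
  colnames(values) <- channels
  structure(list(values = values, bin_dt = bin_dt, channels = channels),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity_trace: %d bins x %d channel(s), bin_dt = %g s (%.3g s total)\n",
              nrow(x$values), ncol(x$values), x$bin_dt,
              nrow(x$values) * x$bin_dt))
  invisible(x)
}

.resolve_channel <- function(trace, ch) {
  if (is.character(ch)) ch <- match(ch, trace$channels)
  if (is.na(ch) || ch < 1L || ch > ncol(trace$values))
    stop("unknown channel")
  as.integer(ch)
}

#' Correlation curve container
#'
#' @param lag numeric, lag times in seconds, strictly increasing.
#' @param G dimensionless correlation amplitudes,
#'   G(tau) = <dIa(t) dIb(t+tau)> / (<Ia><Ib>).
#' @param sd per-lag standard deviation (e.g. over replicate curves); `NA`
#'   when only a single curve is available.
#' @param pair which channel pair the curve describes, e.g. `"green-green"`,
#'   `"red-red"`, `"green-red"`.
#' @return a `data.frame` of class `correlation_curve` with columns
#'   `lag`, `G`, `sd` and attribute `pair`.
#' @export
correlation_curve <- function(lag, G, sd = NA_real_, pair = "auto") {
  stopifnot(length(lag) == length(G), all(diff(lag) > 0))
  sd <- rep_len(as.numeric(sd), length(lag))
  if (any(!is.na(sd) & sd < 0)) stop("per-lag sd must be >= 0")
  out <- data.frame(lag = as.numeric(lag), G = as.numeric(G), sd = sd)
  attr(out, "pair") <- pair
  class(out) <- c("correlation_curve", "data.frame")
  out
}

## Quasi-logarithmic lag grid (in bins): unit spacing for the first m lags,
## then spacing doubling every m/2 channels, as in commercial multiple-tau
## correlators.
.multitau_lags <- function(n_bins, m = 16L, max_lag_bins) {
  stopifnot(m >= 2L, m %% 2L == 0L)
  lags <- seq_len(m)
  spacing <- 2L
  while (max(lags) < max_lag_bins) {
    nxt <- max(lags) + spacing * seq_len(m %/% 2L)
    lags <- c(lags, nxt)
    spacing <- spacing * 2L
  }
  lags[lags <= max_lag_bins]
}

## Exact symmetric-normalized lagged-product estimator at a set of lags
## (in bins).  Evaluated at full trace resolution for every lag.
.correlate_at_lags <- function(x, y, lags) {
  n <- length(x)
  vapply(lags, function(L) {
    xs <- x[seq_len(n - L)]
    ys <- y[seq.int(L + 1L, n)]
    mx <- mean(xs); my <- mean(ys)
    if (mx == 0 || my == 0)
      stop("undefined correlation normalization: zero mean intensity in an averaging window")
    mean(xs * ys) / (mx * my) - 1
  }, numeric(1))
}

#' Multiple-tau correlation of an intensity trace
#'
#' Software replacement for a multichannel hardware correlator.  Lags are
#' placed on a quasi-logarithmic grid (unit bin spacing for the first `m`
#' lags, then the spacing doubles every `m/2` channels).  Unlike a hardware
#' correlator the estimator is evaluated exactly at full trace resolution
#' for every lag, with symmetric normalization (each averaging window uses
#' its own mean), so the result is identical to [direct_correlation()] on
#' shared lags.
#'
#' @param trace an [intensity_trace()].
#' @param channel_a,channel_b channel index or name; equal channels give the
#'   autocorrelation.
#' @param m number of unit-spaced lag channels before the spacing starts to
#'   double (default 16, even).
#' @param max_lag maximum lag in seconds; defaults to an eighth of the trace
#'   duration, beyond which the estimator variance grows steeply.
#' @return a [correlation_curve()].
#' @export
multiple_tau <- function(trace, channel_a = 1L, channel_b = channel_a,
                         m = 16L, max_lag = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  a <- .resolve_channel(trace, channel_a)
  b <- .resolve_channel(trace, channel_b)
  n <- nrow(trace$values)
  if (n < 2L * m) stop("trace must contain at least 2*m bins")
  if (is.null(max_lag)) max_lag <- n * trace$bin_dt / 8
  max_lag_bins <- max(1L, floor(max_lag / trace$bin_dt))
  max_lag_bins <- min(max_lag_bins, n - 2L)
  x <- trace$values[, a]
  y <- trace$values[, b]
  if (all(x == 0) || all(y == 0))
    stop("undefined correlation normalization: constant-zero trace")
  lags <- .multitau_lags(n, as.integer(m), max_lag_bins)
  G <- .correlate_at_lags(x, y, lags)
  pair <- if (a == b) paste0(trace$channels[a], "-", trace$channels[a]) else
    paste0(trace$channels[a], "-", trace$channels[b])
  correlation_curve(lags * trace$bin_dt, G, pair = pair)
}

#' Direct lagged-product correlation (linear lag grid)
#'
#' Exact O(N L) estimator on the linear lag grid 1..`max_lag_bins`, with the
#' same symmetric normalization as [multiple_tau()].  Intended as a
#' brute-force reference for short traces.
#'
#' @inheritParams multiple_tau
#' @param max_lag_bins maximum lag in bins (must be < trace length - 1).
#' @param include_zero also report the zero-lag point (for an
#'   autocorrelation, G(0) = var/mean^2 including shot noise); off by
#'   default, matching the correlator convention.
#' @return a [correlation_curve()].
#' @export
direct_correlation <- function(trace, channel_a = 1L, channel_b = channel_a,
                               max_lag_bins, include_zero = FALSE) {
  stopifnot(inherits(trace, "intensity_trace"))
  a <- .resolve_channel(trace, channel_a)
  b <- .resolve_channel(trace, channel_b)
  n <- nrow(trace$values)
  max_lag_bins <- as.integer(max_lag_bins)
  if (max_lag_bins >= n - 1L) stop("max_lag_bins must be < trace length - 1")
  x <- trace$values[, a]
  y <- trace$values[, b]
  if (all(x == 0) || all(y == 0))
    stop("undefined correlation normalization: constant-zero trace")
  lags <- if (include_zero) 0:max_lag_bins else seq_len(max_lag_bins)
  G <- .correlate_at_lags(x, y, lags)
  pair <- paste0(trace$channels[a], "-", trace$channels[b])
  correlation_curve(lags * trace$bin_dt, G, pair = pair)
}

#' Average replicate correlation curves
#'
#' Per-lag mean and standard deviation over repeated measurements; the SD is
#' the weighting used by the model fit.
#'
#' @param curves list of [correlation_curve()]s on the identical lag grid.
#' @return a [correlation_curve()] with `sd` filled in.
#' @export
average_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 2L)
  lag0 <- curves[[1]]$lag
  for (cv in curves) {
    stopifnot(inherits(cv, "correlation_curve"))
    if (length(cv$lag) != length(lag0) || any(cv$lag != lag0))
      stop("curves must share an identical lag grid")
  }
  Gm <- sapply(curves, `[[`, "G")
  correlation_curve(lag0,
                    rowMeans(Gm),
                    sd = apply(Gm, 1L, sd),
                    pair = attr(curves[[1]], "pair"))
}

#' Write / read correlation curves as CSV
#'
#' Column layout: `lag_s, G, sd, pair`.
#' @param curve a [correlation_curve()].
#' @param path file path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(lag_s = curve$lag, G = curve$G, sd = curve$sd,
                   pair = attr(curve, "pair"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path)
  need <- c("lag_s", "G", "sd", "pair")
  if (!all(need %in% names(df)))
    stop("malformed correlation-curve CSV: expected columns ", paste(need, collapse = ", "))
  correlation_curve(df$lag_s, df$G, df$sd, pair = df$pair[1])
}
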