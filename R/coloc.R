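#' Detect diffraction-limited spots in a single frame
#'
#' Band-pass (difference-of-Gaussians) detection at scales matched to the
#' expected spot diameter range, followed by local-maximum selection above a
#' contrast threshold and sub-pixel centroid refinement.  Defaults match
#' detection of 0.27-0.35 um objects on 120 nm pixels.
#'
#' @param frame numeric matrix (one image frame).
#' @param pixel_size micrometres per pixel.
#' @param diameter_range_um expected spot FWHM range, micrometres.
#' @param contrast minimum band-pass response for a detection; `NULL`
#'   (default) uses a robust automatic threshold of
#'   `k_auto x mad(response)`.
#' @param k_auto multiplier for the automatic contrast threshold.
#' @return data.frame `{frame, channel, x_px, y_px, intensity, diameter_px}`
#'   (`intensity` is the band-pass response at the maximum).
#' @export
detect_spots <- function(frame, pixel_size = 0.12,
                         diameter_range_um = c(0.27, 0.35),
                         contrast = NULL, k_auto = 6) {
  stopifnot(is.matrix(frame), pixel_size > 0,
            length(diameter_range_um) == 2L,
            diameter_range_um[1] < diameter_range_um[2])
  mx <- max(frame)
  if (sum(frame == mx) > 5L)
    warning("frame may be saturated: ", sum(frame == mx),
            " pixels at the maximum value")
  sigma_lo <- diameter_range_um[1] / 2.355 / pixel_size
  sigma_hi <- diameter_range_um[2] / 2.355 / pixel_size
  dog <- EBImage::gblur(frame, sigma = sigma_lo) -
    EBImage::gblur(frame, sigma = 2 * sigma_hi)
  ## floor guards against numerically-zero mad on noiseless backgrounds
  if (is.null(contrast))
    contrast <- max(k_auto * mad(dog), 1e-6 * max(dog, 0), 1e-12)
  nx <- nrow(dog); ny <- ncol(dog)
  inner <- dog[2:(nx - 1), 2:(ny - 1)]
  is_max <- inner > contrast
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & inner >= dog[2:(nx - 1) + di, 2:(ny - 1) + dj]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(frame = integer(0), channel = character(0),
                      x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), diameter_px = numeric(0)))
  x <- idx[, 1] + 1L
  y <- idx[, 2] + 1L
  ## sub-pixel centroid on the 3x3 band-pass patch
  xs <- numeric(length(x)); ys <- numeric(length(x))
  for (k in seq_along(x)) {
    patch <- dog[(x[k] - 1L):(x[k] + 1L), (y[k] - 1L):(y[k] + 1L)]
    patch <- pmax(patch, 0)
    w <- sum(patch)
    xs[k] <- x[k] + sum(patch * matrix(-1:1, 3, 3)) / w
    ys[k] <- y[k] + sum(patch * matrix(-1:1, 3, 3, byrow = TRUE)) / w
  }
  data.frame(frame = 1L, channel = "unknown", x_px = xs, y_px = ys,
             intensity = dog[cbind(x, y)],
             diameter_px = mean(diameter_range_um) / pixel_size)
}

#' Mutual-nearest-neighbor matching of two spot tables
#'
#' A pair is formed when spot a's nearest neighbor in table B is b, b's
#' nearest neighbor in A is a, and their distance is within `radius_px`;
#' every spot enters at most one pair.
#'
#' @param tableA,tableB data.frames with columns `x_px`, `y_px`.
#' @param radius_px matching radius, pixels (default ~1 PSF sigma = 2 px).
#' @return data.frame `{idxA, idxB, dist_px}` (possibly empty).
#' @export
match_spots <- function(tableA, tableB, radius_px = 2) {
  empty <- data.frame(idxA = integer(0), idxB = integer(0),
                      dist_px = numeric(0))
  if (nrow(tableA) == 0L || nrow(tableB) == 0L) return(empty)
  dx <- outer(tableA$x_px, tableB$x_px, `-`)
  dy <- outer(tableA$y_px, tableB$y_px, `-`)
  d <- sqrt(dx^2 + dy^2)
  nnA <- apply(d, 1L, which.min)   # for each A, closest B
  nnB <- apply(d, 2L, which.min)   # for each B, closest A
  ia <- which(nnB[nnA] == seq_len(nrow(tableA)))
  ib <- nnA[ia]
  dd <- d[cbind(ia, ib)]
  ok <- dd <= radius_px
  data.frame(idxA = ia[ok], idxB = ib[ok], dist_px = dd[ok])
}

#' Dye labeling efficiency from two-channel particle fields
#'
#' L_eff = mean over fields of (dye-positive spots) / (spots positive for
#' dye or reporter).  Fields with an empty union are excluded with a
#' warning.
#'
#' @param dye_counts,union_counts per-field counts (equal length, >= 1
#'   field).
#' @return list with `L_eff` (the mean), `per_field`, `sd`.
#' @export
labeling_efficiency <- function(dye_counts, union_counts) {
  stopifnot(length(dye_counts) == length(union_counts),
            length(dye_counts) >= 1L,
            all(dye_counts >= 0), all(union_counts >= 0),
            all(dye_counts <= union_counts))
  ok <- union_counts > 0
  if (!all(ok)) warning(sum(!ok), " field(s) with empty union excluded")
  if (!any(ok)) stop("no field has a non-empty union")
  per <- dye_counts[ok] / union_counts[ok]
  list(L_eff = mean(per), per_field = per,
       sd = if (length(per) > 1L) sd(per) else NA_real_)
}

#' Corrected fraction of species A bound to species B
#'
#' Raw coincidence (matched A spots / total A spots) is corrected for
#' chance colocalization measured with a negative-control pair
#' (renormalization `(raw - f_c)/(1 - f_c)`), for incomplete dye labeling
#' of the B channel (`/ L_eff`), and for heterozygous tagging of B
#' (`x heterozygosity`), then clipped to `[0, 1]`.
#'
#' @param tableA,tableB spot tables (`x_px`, `y_px`); A is the species whose
#'   bound fraction is reported.
#' @param L_eff labeling efficiency of the B-channel dye in `(0, 1]` (1 when
#'   B is a fully fluorescent tag).
#' @param heterozygosity correction factor for B's tagged-allele share
#'   (2 when B is heterozygously tagged, else 1).
#' @param f_c chance-colocalization fraction from the negative control, in
#'   `[0, 1)`.
#' @param radius_px matching radius for [match_spots()].
#' @return object of class `coupling_estimate`: list with `raw`,
#'   `corrected`, `corrections` (the factors applied), `n_A`, `n_matched`.
#' @export
fraction_bound <- function(tableA, tableB, L_eff = 1, heterozygosity = 1,
                           f_c = 0, radius_px = 2) {
  if (L_eff <= 0) stop("L_eff must be positive")
  stopifnot(L_eff <= 1, f_c >= 0, f_c < 1, heterozygosity >= 1,
            nrow(tableA) >= 1L)
  m <- match_spots(tableA, tableB, radius_px)
  raw <- nrow(m) / nrow(tableA)
  corrected <- (raw - f_c) / (1 - f_c) / L_eff * heterozygosity
  corrected <- min(max(corrected, 0), 1)
  structure(list(raw = raw, corrected = corrected,
                 corrections = list(L_eff = L_eff,
                                    heterozygosity = heterozygosity,
                                    f_c = f_c, radius_px = radius_px),
                 n_A = nrow(tableA), n_matched = nrow(m)),
            class = "coupling_estimate")
}

#' @export
print.coupling_estimate <- function(x, ...) {
  cat(sprintf("coupling_estimate: raw = %.3f, corrected = %.3f (n_A = %d, matched = %d)\n",
              x$raw, x$corrected, x$n_A, x$n_matched))
  cat(sprintf("  corrections: L_eff = %.3g, heterozygosity = %g, f_c = %.3g\n",
              x$corrections$L_eff, x$corrections$heterozygosity,
              x$corrections$f_c))
  invisible(x)
}
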