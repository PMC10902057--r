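# Spectral preprocessing: per-pixel ppm alignment against the cohort mean
# spectrum, TIC normalization, average spectrum, peak picking on the
# average spectrum, and reduction of the datacube to a pixels x peaks
# feature matrix.

# Linear resampling of all rows of `I` (pixels x m/z on `axis`) at the
# positions axis*(1 + ppm*1e-6). Shared positions across rows keeps this a
# pure matrix operation.
.resample_rows <- function(I, axis, ppm, cols = seq_along(axis)) {
  pos <- axis[cols] * (1 + ppm * 1e-6)
  n <- length(axis)
  i <- findInterval(pos, axis, all.inside = TRUE)
  w <- (pos - axis[i]) / (axis[i + 1] - axis[i])
  w <- pmin(pmax(w, 0), 1)
  # clamp positions outside the axis to the edge value
  lo <- matrix(rep(1 - w, each = nrow(I)), nrow(I))
  I[, i, drop = FALSE] * lo + I[, i + 1, drop = FALSE] * (1 - lo)
}

#' Align pixel spectra by a rigid ppm shift
#'
#' Estimates, for every pixel, the parts-per-million mass shift that
#' maximizes the normalized cross-correlation between the pixel spectrum
#' (resampled at the candidate shift) and the cohort mean spectrum, over a
#' grid search in `[-max_shift_ppm, max_shift_ppm]` with parabolic
#' sub-grid refinement, run in two passes (the mean spectrum is recomputed
#' from the corrected cube between passes). Each spectrum is then
#' resampled onto the common axis at its estimated shift.
#'
#' @param cube a `spectra_cube` (shared-axis matrix form).
#' @param max_shift_ppm search half-width in ppm (> 0).
#' @param grid_step_ppm search grid resolution (default 0.5 ppm).
#' @param passes number of estimate/correct passes (default 2).
#' @return list: `cube` (corrected), `shift_ppm` (per-pixel estimates; the
#'   injected drift is recovered with the same sign), `flagged` (logical:
#'   all-zero pixels, shift forced to 0) and `saturated` (logical:
#'   estimate hit the search bound).
#' @export
align_spectra <- function(cube, max_shift_ppm = 10, grid_step_ppm = 0.5,
                          passes = 2) {
  stopifnot(inherits(cube, "spectra_cube"), max_shift_ppm > 0,
            grid_step_ppm > 0, passes >= 1)
  I <- cube$intensity
  if (nrow(I) == 0) stop("empty cube")
  zero <- rowSums(I) == 0
  total <- rep(0, nrow(I))
  for (pass in seq_len(passes)) {
    ref <- colMeans(I[!zero, , drop = FALSE])
    active <- which(ref > 1e-5 * max(ref))
    if (length(active) < 4) active <- seq_along(ref)
    refa <- ref[active]
    refa <- refa - mean(refa)
    grid <- seq(-max_shift_ppm, max_shift_ppm, by = grid_step_ppm)
    score <- matrix(-Inf, nrow(I), length(grid))
    for (k in seq_along(grid)) {
      R <- .resample_rows(I, cube$mz, grid[k], cols = active)
      R <- R - rowMeans(R)
      s <- as.vector(R %*% refa) / sqrt(rowSums(R * R))
      s[!is.finite(s)] <- -Inf
      score[, k] <- s
    }
    best <- max.col(score, ties.method = "first")
    est <- grid[best]
    # parabolic refinement where the peak is interior
    interior <- best > 1 & best < length(grid)
    if (any(interior)) {
      ii <- which(interior)
      y1 <- score[cbind(ii, best[ii] - 1L)]
      y2 <- score[cbind(ii, best[ii])]
      y3 <- score[cbind(ii, best[ii] + 1L)]
      den <- (y1 - 2 * y2 + y3)
      off <- ifelse(abs(den) > 0, 0.5 * (y1 - y3) / den, 0)
      off <- pmin(pmax(off, -1), 1)
      est[ii] <- est[ii] + off * grid_step_ppm
    }
    est[zero] <- 0
    # estimates under half a grid step are indistinguishable from zero;
    # snapping avoids needless resampling of already-aligned spectra
    est[abs(est) < grid_step_ppm / 2] <- 0
    # cap the cumulative shift at the search bound
    est <- pmin(pmax(est, -max_shift_ppm - total), max_shift_ppm - total)
    total <- total + est
    for (p in which(est != 0)) {
      pos <- cube$mz * (1 + est[p] * 1e-6)
      I[p, ] <- stats::approx(cube$mz, I[p, ], xout = pos, rule = 2)$y
    }
  }
  cube$intensity <- I
  saturated <- abs(total) >= max_shift_ppm - 1e-9
  list(cube = cube, shift_ppm = total, flagged = zero, saturated = saturated)
}

#' Total-ion-current normalization
#'
#' Scales every pixel spectrum (or feature-matrix row) so its summed
#' intensity is 1. Pixels with zero total signal are left as zeros and
#' flagged rather than raising an error; downstream correlation analysis
#' excludes them.
#'
#' @param x a `spectra_cube` or a numeric matrix (rows = pixels).
#' @return list: `data` (same type as input, normalized), `tic` (original
#'   per-pixel totals), `flagged` (logical, all-zero pixels).
#' @export
tic_normalize <- function(x) {
  I <- if (inherits(x, "spectra_cube")) x$intensity else as.matrix(x)
  if (any(I < 0)) stop("negative intensities")
  tic <- rowSums(I)
  flagged <- tic == 0
  scale <- ifelse(flagged, 1, tic)
  I <- I / scale
  if (inherits(x, "spectra_cube")) {
    x$intensity <- I
    list(data = x, tic = tic, flagged = flagged)
  } else {
    list(data = I, tic = tic, flagged = flagged)
  }
}

#' Average spectrum of a cube
#'
#' Pointwise mean over the selected pixels on the cube's common m/z axis.
#'
#' @param cube a `spectra_cube`.
#' @param pixels integer indices of pixels to include (default: all pixels
#'   with nonzero signal).
#' @return list of class `avg_spectrum`: `mz`, `intensity`.
#' @export
average_spectrum <- function(cube, pixels = NULL) {
  stopifnot(inherits(cube, "spectra_cube"))
  if (nrow(cube$intensity) == 0) stop("empty cube")
  if (is.null(pixels)) pixels <- which(rowSums(cube$intensity) > 0)
  if (length(pixels) == 0) stop("no non-empty pixels to average")
  structure(list(mz = cube$mz,
                 intensity = colMeans(cube$intensity[pixels, , drop = FALSE])),
            class = "avg_spectrum")
}

#' Pick peaks from an average spectrum
#'
#' Local maxima (strictly greater than both neighbours) of the optionally
#' smoothed average spectrum whose (unsmoothed) apex intensity is at least
#' `threshold_fraction` of the strongest signal. The default threshold of
#' 0.5% of the base peak is the reduction rule the rest of the pipeline is
#' built on.
#'
#' @param avg an `avg_spectrum`, or a list with `mz` and `intensity`.
#' @param threshold_fraction minimum apex intensity as a fraction of the
#'   global maximum, in `[0, 1]` (default 0.005).
#' @param smooth moving-average window (odd; `0` or `1` disables
#'   smoothing; default 3).
#' @return object of class `peaklist`: data.frame-like list with `mz`
#'   (strictly increasing) and `intensity` (apex values in the average
#'   spectrum).
#' @export
pick_peaks <- function(avg, threshold_fraction = 0.005, smooth = 3) {
  stopifnot(threshold_fraction >= 0, threshold_fraction <= 1)
  y <- avg$intensity
  mz <- avg$mz
  if (length(y) == 0) stop("empty spectrum")
  ys <- if (smooth >= 2) stats::filter(y, rep(1 / smooth, smooth), sides = 2) else y
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  if (n < 3) {
    apex <- integer(0)
  } else {
    apex <- which(ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] > ys[3:n]) + 1L
  }
  keep <- y[apex] >= threshold_fraction * max(y)
  apex <- apex[keep]
  structure(list(mz = mz[apex], intensity = y[apex],
                 threshold_fraction = threshold_fraction),
            class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %d peaks, m/z %.4f .. %.4f (threshold %.3g x base peak)\n",
              length(x$mz), min(x$mz), max(x$mz), x$threshold_fraction))
  invisible(x)
}

#' Reduce a cube to a pixels x peaks feature matrix
#'
#' For every pixel and every peak, the entry is the maximum intensity
#' within `tol_ppm` of the peak centre (0 where there is no signal). Each
#' spectral point feeds at most one peak; where windows of neighbouring
#' peaks overlap, points go to the nearest centre (a warning is logged).
#'
#' @param cube a `spectra_cube` (aligned and normalized).
#' @param peaklist a `peaklist` or numeric vector of peak centres.
#' @param tol_ppm extraction half-window in ppm (default 5).
#' @return object of class `feature_matrix`: list with `values` (pixels x
#'   peaks), `mz` (peak centres), `coords`, `tol_ppm`.
#' @export
reduce_cube <- function(cube, peaklist, tol_ppm = 5) {
  stopifnot(inherits(cube, "spectra_cube"), tol_ppm > 0)
  centers <- if (inherits(peaklist, "peaklist")) peaklist$mz else as.numeric(peaklist)
  if (length(centers) == 0) stop("empty peak list")
  centers <- sort(centers)
  axis <- cube$mz
  # assign axis points to peak windows, nearest centre on overlap
  nearest <- findInterval(axis, centers)
  low <- pmax(nearest, 1L)
  high <- pmin(nearest + 1L, length(centers))
  d_low <- abs(axis - centers[low])
  d_high <- abs(axis - centers[high])
  assigned <- ifelse(d_low <= d_high, low, high)
  dist_ppm <- abs(axis - centers[assigned]) / centers[assigned] * 1e6
  in_win <- dist_ppm <= tol_ppm
  # overlap check: any point within tol of two centres
  other <- ifelse(assigned == low, high, low)
  overlap <- in_win & other != assigned &
    abs(axis - centers[other]) / centers[other] * 1e6 <= tol_ppm
  if (any(overlap)) {
    warning(sprintf("%d spectral points fall in overlapping peak windows; nearest-centre rule applied",
                    sum(overlap)))
  }
  V <- matrix(0, nrow(cube$intensity), length(centers))
  for (k in seq_along(centers)) {
    idx <- which(in_win & assigned == k)
    if (length(idx) == 0) next
    if (length(idx) == 1L) {
      V[, k] <- cube$intensity[, idx]
    } else {
      V[, k] <- do.call(pmax, as.data.frame(cube$intensity[, idx, drop = FALSE]))
    }
  }
  structure(list(values = V, mz = centers, coords = cube$coords,
                 tol_ppm = tol_ppm, width_px = cube$width_px,
                 height_px = cube$height_px),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d pixels x %d peaks (tol %.3g ppm)\n",
              nrow(x$values), ncol(x$values), x$tol_ppm))
  invisible(x)
}

#' Identify tissue pixels from the TIC distribution
#'
#' Background pixels carry only baseline signal; tissue pixels carry the
#' lipid load. Either a fixed TIC quantile cut or Otsu's threshold on
#' log-TIC separates them.
#'
#' @param tic numeric vector of per-pixel total ion currents.
#' @param method `"otsu"` (default; bimodal log-TIC) or `"quantile"`.
#' @param quantile cut point for `method = "quantile"` (default 0.05).
#' @return integer indices of tissue pixels.
#' @export
tissue_pixels <- function(tic, method = c("otsu", "quantile"),
                          quantile = 0.05) {
  method <- match.arg(method)
  pos <- tic > 0
  if (method == "quantile") {
    thr <- stats::quantile(tic[pos], quantile)
    return(which(tic >= thr & pos))
  }
  lt <- log(tic[pos])
  # unimodal guard: if all positive TICs sit within a factor e of each
  # other there is no background mode to cut away
  if (diff(range(lt)) < 1) return(which(pos))
  breaks <- seq(min(lt), max(lt), length.out = 257)
  h <- hist(lt, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p); mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  thr <- mids[which.max(between)]
  which(pos)[lt > thr]
}

#' Run the full preprocessing chain on a cube
#'
#' Pipeline order: align, TIC-normalize, average, pick peaks, reduce.
#'
#' @param cube a `spectra_cube`.
#' @param max_shift_ppm alignment search bound (ppm).
#' @param threshold_fraction peak-picking threshold (fraction of base peak).
#' @param tol_ppm extraction tolerance (ppm).
#' @param tissue_method background exclusion method (see
#'   [tissue_pixels()]); tissue is detected on the pre-normalization TIC.
#' @return list of class `preprocessed`: `features` (a `feature_matrix`
#'   restricted to tissue pixels), `peaklist`, `avg` (average spectrum),
#'   `shift_ppm`, `tic`, `tissue_idx` (pixel indices into the original
#'   cube), `flagged`.
#' @export
preprocess_cube <- function(cube, max_shift_ppm = 10,
                            threshold_fraction = 0.005, tol_ppm = 5,
                            tissue_method = "otsu") {
  al <- align_spectra(cube, max_shift_ppm = max_shift_ppm)
  nz <- tic_normalize(al$cube)
  tissue_idx <- tissue_pixels(nz$tic, method = tissue_method)
  avg <- average_spectrum(nz$data, pixels = tissue_idx)
  pl <- pick_peaks(avg, threshold_fraction = threshold_fraction)
  fm <- reduce_cube(nz$data, pl, tol_ppm = tol_ppm)
  fm$values <- fm$values[tissue_idx, , drop = FALSE]
  fm$coords <- fm$coords[tissue_idx, , drop = FALSE]
  fm$pixel_index <- tissue_idx
  structure(list(features = fm, peaklist = pl, avg = avg,
                 shift_ppm = al$shift_ppm, tic = nz$tic,
                 tissue_idx = tissue_idx,
                 flagged = nz$flagged | al$flagged),
            class = "preprocessed")
}

#' @export
print.preprocessed <- function(x, ...) {
  cat(sprintf("<preprocessed> %d tissue pixels, %d peaks\n",
              nrow(x$features$values), length(x$peaklist$mz)))
  invisible(x)
}
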