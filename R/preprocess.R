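#' Split time-domain signals into the low and high frequency bands
#'
#' Zero-phase ideal (FFT-mask) band-pass filtering of per-position
#' ultrasound time series into the 10-40 MHz (low) and 40-120 MHz (high)
#' bands used for band-selected reconstruction. Exists to exercise the
#' band definitions on synthetic signals; real data enter the pipeline as
#' reconstructed volumes.
#'
#' @param signals numeric vector (one A-line) or matrix with one time
#'   series per column.
#' @param fs sampling rate in Hz; must exceed 240 MHz (Nyquist for the
#'   120 MHz band edge).
#' @param bands list of two `c(lo, hi)` band edges in Hz. Band membership
#'   is half-open `(lo, hi]` so the shared 40 MHz edge belongs to the low
#'   band only.
#' @return A list with elements `low` and `high`, same shape as input.
#' @export
bandpassSplit <- function(signals, fs,
                          bands = list(low = c(10e6, 40e6),
                                       high = c(40e6, 120e6))) {
  if (fs <= 2 * max(unlist(bands)))
    stop("sampling rate too low: need fs > ", 2 * max(unlist(bands)), " Hz")
  v <- as.matrix(signals)
  n <- nrow(v)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)          # two-sided magnitude frequency
  out <- lapply(bands, function(b) {
    keep <- freq > b[1] & freq <= b[2]
    ftr <- apply(v, 2, function(col) {
      F <- stats::fft(col)
      F[!keep] <- 0
      Re(stats::fft(F, inverse = TRUE)) / n
    })
    if (is.null(dim(signals))) as.numeric(ftr) else ftr
  })
  names(out) <- names(bands)
  out
}

#' Detect the skin surface of a volume
#'
#' Per lateral position, the surface is the first depth at which the
#' depth-smoothed A-line exceeds a fraction of its own maximum; the
#' resulting depth map is then median-filtered laterally to suppress
#' outliers. Columns with no signal are filled from their neighbours.
#'
#' @param grid a [VolumeGrid-class] with non-negative intensities.
#' @param thresholdFraction fraction of the per-column smoothed maximum
#'   (default 0.5).
#' @param smoothVoxels depth moving-average window (voxels, default 5).
#' @param medianWindow lateral median-filter window (default 3).
#' @return A numeric (fast x slow) matrix of surface depths in um, with
#'   attribute `"rows"` holding the integer depth rows.
#' @export
detectSurface <- function(grid, thresholdFraction = 0.5, smoothVoxels = 5,
                          medianWindow = 3) {
  v <- grid@values
  if (all(v == 0)) stop("cannot detect a surface in an all-zero volume")
  d <- dim(v)
  k <- smoothVoxels + (1 - smoothVoxels %% 2)   # force odd window
  sm <- conv1dAlong(v, rep(1 / k, k), 1)
  rows <- matrix(NA_real_, d[2], d[3])
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    col <- sm[, j, k]
    m <- max(col)
    if (m <= 0) next
    hit <- which(col > thresholdFraction * m)
    rows[j, k] <- hit[1]
  }
  if (anyNA(rows)) {
    fill <- stats::median(rows, na.rm = TRUE)
    if (is.na(fill)) stop("cannot detect a surface in an all-zero volume")
    # fill empty columns from the median of available lateral neighbours
    nas <- which(is.na(rows), arr.ind = TRUE)
    for (r in seq_len(nrow(nas))) {
      i <- nas[r, 1]; j <- nas[r, 2]
      nb <- rows[max(1, i - 1):min(d[2], i + 1),
                 max(1, j - 1):min(d[3], j + 1)]
      rows[i, j] <- if (all(is.na(nb))) fill else
        stats::median(nb, na.rm = TRUE)
    }
  }
  rows <- medianFilter2d(rows, medianWindow)
  depth <- grid@originDepth + (rows - 1) * grid@spacing[1]
  attr(depth, "rows") <- rows
  depth
}

#' Flatten a volume so the skin surface is at a common depth
#'
#' Each A-line is shifted by an integer number of depth voxels so the
#' detected surface lands on a common reference row (the minimum surface
#' row by default, so no signal is pushed off the top). Shifts are
#' integer-voxel, intensities are untouched, out-of-range voxels are
#' zero-filled. The applied shifts are retained as the `"shifts"`
#' attribute of the returned values for inverse mapping, and flattening
#' an already-flat volume is the identity.
#'
#' @param grid a [VolumeGrid-class].
#' @param surface surface map from [detectSurface()] (um, with a `"rows"`
#'   attribute) or a numeric matrix of depth rows.
#' @param referenceDepthUm optional target depth (um) for the surface;
#'   default aligns to the shallowest detected surface.
#' @return A flattened [VolumeGrid-class].
#' @export
flattenVolume <- function(grid, surface, referenceDepthUm = NULL) {
  rows <- attr(surface, "rows")
  if (is.null(rows))
    rows <- (surface - grid@originDepth) / grid@spacing[1] + 1
  rows <- round(rows)
  refRow <- if (is.null(referenceDepthUm)) min(rows) else
    round((referenceDepthUm - grid@originDepth) / grid@spacing[1]) + 1
  d <- dim(grid@values)
  out <- array(0, d)
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- rows[j, k] - refRow            # shift up by s voxels
    if (s == 0) {
      out[, j, k] <- grid@values[, j, k]
    } else if (s > 0) {
      out[1:(d[1] - s), j, k] <- grid@values[(s + 1):d[1], j, k]
    } else {
      out[(1 - s):d[1], j, k] <- grid@values[1:(d[1] + s), j, k]
    }
  }
  res <- VolumeGrid(out, spacing = grid@spacing, band = grid@band,
                    originDepth = grid@originDepth)
  attr(res@values, "shifts") <- rows - refRow
  attr(res@values, "referenceRow") <- refRow
  res
}

#' Flatten both bands of a pair with the surface of one band
#'
#' The surface is detected on the chosen band (the low band by default,
#' which carries the strong epidermis signal) and the same integer shifts
#' are applied to both volumes so they stay co-registered.
#'
#' @param pair a [BandPair-class].
#' @param on band used for surface detection.
#' @param ... passed to [detectSurface()].
#' @return A flattened [BandPair-class].
#' @export
flattenPair <- function(pair, on = c("low", "high"), ...) {
  on <- match.arg(on)
  ref <- if (on == "low") pair@low else pair@high
  surf <- detectSurface(ref, ...)
  BandPair(flattenVolume(pair@low, surf),
           flattenVolume(pair@high, surf),
           weight = pair@weight)
}
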