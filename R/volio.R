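#' Construct a VolumeGrid
#'
#' @param values 3D numeric array with axis order (depth, fast, slow).
#' @param spacing voxel spacing in um per axis; default `c(3, 12, 12)`,
#'   the reconstruction grid of the imaging system.
#' @param band frequency band label: `"low"`, `"high"` or `"full"`.
#' @param originDepth depth (um) of the first slice.
#' @return A [VolumeGrid-class].
#' @export
VolumeGrid <- function(values, spacing = c(3, 12, 12), band = "full",
                       originDepth = 0) {
  new("VolumeGrid", values = values, spacing = as.numeric(spacing),
      band = band, originDepth = as.numeric(originDepth))
}

#' Construct a BandPair
#'
#' @param low,high the two band volumes ([VolumeGrid-class]); same shape
#'   and spacing.
#' @param weight high-band weighting factor for composite fusion. When
#'   `NULL`, it is chosen so the 95th percentile of the unit-normalized
#'   high band matches that of the unit-normalized low band.
#' @return A [BandPair-class].
#' @export
BandPair <- function(low, high, weight = NULL) {
  if (is.null(weight)) weight <- defaultFusionWeight(low, high)
  new("BandPair", low = low, high = high, weight = weight)
}

defaultFusionWeight <- function(low, high) {
  ql <- stats::quantile(normalizeUnit(low@values), 0.95, names = FALSE)
  qh <- stats::quantile(normalizeUnit(high@values), 0.95, names = FALSE)
  if (qh <= 0) return(1)
  ql / qh
}

normalizeUnit <- function(x) {
  m <- max(x)
  if (m > 0) x / m else x
}

sidecarPath <- function(path) {
  base <- sub("\\.nii\\.gz$", "", path)
  paste0(tools::file_path_sans_ext(base), ".json")
}

writeSidecar <- function(path, grid, extra = list()) {
  meta <- c(list(
    shape = dim(grid@values),
    spacing_um = grid@spacing,
    band = grid@band,
    origin_depth_um = grid@originDepth
  ), extra)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read a band volume from disk
#'
#' Supported formats: multi-page TIFF (one page per depth slice), NIfTI-1,
#' and raw float32. All formats use a JSON metadata sidecar
#' (`<stem>.json`) holding `shape`, `spacing_um`, `band` and
#' `origin_depth_um`; TIFF sidecars additionally hold `intensity_scale`
#' because TIFF pages store unit-normalized values. Without a sidecar the
#' default spacing `c(3, 12, 12)` um is assumed with a warning. The
#' returned axis order is always (depth, fast, slow).
#'
#' @param path file path (`.tif`/`.tiff`, `.nii`/`.nii.gz`, `.raw`/`.bin`).
#' @param metadata optional list overriding/augmenting the sidecar.
#' @return A [VolumeGrid-class].
#' @export
readVolume <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- readSidecar(path)
  if (!is.null(metadata)) meta <- utils::modifyList(meta %||% list(), metadata)
  if (is.null(meta$spacing_um)) {
    warning("no metadata sidecar for ", basename(path),
            "; assuming default spacing (3, 12, 12) um")
    meta$spacing_um <- c(3, 12, 12)
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  vals <- switch(ext,
    tif = , tiff = {
      pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                        error = function(e) stop("TIFF format error: ",
                                                 conditionMessage(e)))
      if (!length(pages)) stop("TIFF format error: no pages")
      arr <- array(0, c(length(pages), dim(pages[[1]])))
      for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
      arr * (meta$intensity_scale %||% 1) + (meta$intensity_offset %||% 0)
    },
    nii = {
      a <- unclass(RNifti::readNifti(path))
      array(as.numeric(a), dim(a))
    },
    raw = , bin = {
      if (is.null(meta$shape)) stop("raw format requires 'shape' metadata")
      n <- prod(meta$shape)
      if (file.info(path)$size != 4 * n)
        stop("raw format error: file size/shape mismatch for ",
             basename(path))
      con <- file(path, "rb")
      on.exit(close(con))
      v <- readBin(con, "numeric", n = n, size = 4)
      array(v, meta$shape)
    },
    stop("unsupported volume format: .", ext)
  )
  if (!is.null(meta$shape) && !identical(as.integer(dim(vals)),
                                         as.integer(meta$shape)))
    stop("shape/metadata mismatch for ", basename(path))
  VolumeGrid(vals, spacing = meta$spacing_um, band = meta$band %||% "full",
             originDepth = meta$origin_depth_um %||% 0)
}

#' Write a band volume to disk
#'
#' Writes the volume plus its JSON metadata sidecar; `readVolume()` of the
#' result reproduces the grid (exactly for NIfTI, to single precision for
#' TIFF and raw float32).
#'
#' @param grid a [VolumeGrid-class].
#' @param path destination; the format follows the extension (see
#'   [readVolume()]).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(grid, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
    tif = , tiff = {
      # TIFF pages store unit-range values; the affine map back to the
      # original intensities lives in the sidecar
      lo <- min(grid@values); hi <- max(grid@values)
      scale <- if (hi > lo) hi - lo else 1
      pages <- lapply(seq_len(dim(grid@values)[1]),
                      function(i) (grid@values[i, , ] - lo) / scale)
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
      writeSidecar(path, grid, list(intensity_scale = scale,
                                    intensity_offset = lo))
    },
    nii = {
      RNifti::writeNifti(grid@values, path, datatype = "double")
      writeSidecar(path, grid)
    },
    raw = , bin = {
      con <- file(path, "wb")
      writeBin(as.numeric(grid@values), con, size = 4)
      close(con)
      writeSidecar(path, grid)
    },
    stop("unsupported volume format: .", ext)
  )
  invisible(path)
}

#' Fuse a band pair into a red/green composite
#'
#' Visualization aid mirroring the standard two-band rendering: the low
#' band (large vessels) is mapped to the red channel and the weighted high
#' band (small vessels) to the green channel; blue is zero. Each band is
#' normalized by its own maximum and the result clipped to `[0, 1]`. The
#' composite never feeds biomarker computation.
#'
#' @param pair a [BandPair-class].
#' @return A 4D array `(depth, fast, slow, 3)` of RGB values in `[0, 1]`.
#' @export
fuseComposite <- function(pair) {
  red <- normalizeUnit(pair@low@values)
  green <- pmin(pair@weight * normalizeUnit(pair@high@values), 1)
  d <- dim(red)
  out <- array(0, c(d, 3))
  out[, , , 1] <- pmin(pmax(red, 0), 1)
  out[, , , 2] <- pmax(green, 0)
  out
}

#' Export a maximum intensity projection as PNG
#'
#' @param img 2D numeric matrix (any scale; normalized to `[0, 1]`).
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
writeMipPng <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("PNG export requires the 'png' package")
  png::writePNG(normalizeUnit(pmax(img, 0)), path)
  invisible(path)
}
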