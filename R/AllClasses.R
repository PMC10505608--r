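#' @import methods
NULL

#' VolumeGrid: a single-band 3D intensity field
#'
#' Canonical in-memory representation of one reconstructed RSOM volume.
#' The array axis order is fixed to (depth, fast, slow); depth increases
#' into the skin. Voxel spacing is in micrometres per axis, defaulting to
#' the reconstruction grid of 3 um (depth) x 12 um (fast) x 12 um (slow).
#'
#' @slot values 3D numeric array, axis order (depth, fast, slow).
#' @slot spacing numeric length-3, voxel spacing in um (depth, fast, slow).
#' @slot band one of `"low"` (10-40 MHz), `"high"` (40-120 MHz), `"full"`.
#' @slot originDepth depth (um) of the first depth slice.
#'
#' @exportClass VolumeGrid
setClass("VolumeGrid",
  representation(
    values = "array",
    spacing = "numeric",
    band = "character",
    originDepth = "numeric"
  ),
  prototype(
    spacing = c(3, 12, 12),
    band = "full",
    originDepth = 0
  )
)

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array (depth, fast, slow)")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (um)")
  if (length(object@band) != 1L ||
      !object@band %in% c("low", "high", "full"))
    msg <- c(msg, "'band' must be one of 'low', 'high', 'full'")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (length(msg)) msg else TRUE
})

#' BandPair: co-registered low/high frequency-band volumes
#'
#' Holds the two band-selected reconstructions of one scan plus the
#' weighting factor that modulates the high-band intensity when the two
#' bands are fused into a red/green composite.
#'
#' @slot low low-band (10-40 MHz) [VolumeGrid-class].
#' @slot high high-band (40-120 MHz) [VolumeGrid-class].
#' @slot weight non-negative scalar scaling the high band in composites.
#'
#' @exportClass BandPair
setClass("BandPair",
  representation(low = "VolumeGrid", high = "VolumeGrid", weight = "numeric"),
  prototype(weight = 1)
)

setValidity("BandPair", function(object) {
  msg <- character()
  if (!identical(dim(object@low@values), dim(object@high@values)))
    msg <- c(msg, "low and high band volumes must have identical shape")
  if (!isTRUE(all.equal(object@low@spacing, object@high@spacing)))
    msg <- c(msg, "low and high band volumes must share voxel spacing")
  if (length(object@weight) != 1L || !is.finite(object@weight) ||
      object@weight < 0)
    msg <- c(msg, "'weight' must be a non-negative scalar")
  if (length(msg)) msg else TRUE
})

#' LayerBoundaries: per-stack epidermis top/bottom curves
#'
#' The epidermis is segmented on sagittal MIPs of four 0.5 mm stacks along
#' the slow axis; each stack contributes a top and a bottom boundary curve
#' (depth row index as a function of fast-axis column, possibly fractional
#' after smoothing).
#'
#' @slot top numeric matrix (stacks x fast columns) of top-boundary rows.
#' @slot bottom numeric matrix, same shape, bottom-boundary rows.
#' @slot stackStart integer vector, first slow index of each stack.
#' @slot stackEnd integer vector, last slow index of each stack.
#' @slot spacing voxel spacing (um) of the segmented grid.
#'
#' @exportClass LayerBoundaries
setClass("LayerBoundaries",
  representation(
    top = "matrix",
    bottom = "matrix",
    stackStart = "integer",
    stackEnd = "integer",
    spacing = "numeric"
  )
)

setValidity("LayerBoundaries", function(object) {
  msg <- character()
  if (!identical(dim(object@top), dim(object@bottom)))
    msg <- c(msg, "'top' and 'bottom' must have identical shape")
  if (any(object@bottom < object@top))
    msg <- c(msg, "'bottom' must be >= 'top' everywhere")
  if (length(object@stackStart) != nrow(object@top) ||
      length(object@stackEnd) != nrow(object@top))
    msg <- c(msg, "stack ranges must match the number of boundary rows")
  if (length(msg)) msg else TRUE
})

#' DermisSlab: per-column dermal depth interval
#'
#' The dermis analysis volume starts at the epidermis bottom boundary and
#' extends 1.5 mm deeper; intervals are half-open `[start, end)` in depth
#' rows, one per lateral (fast, slow) position.
#'
#' @slot startRow integer matrix (fast x slow) of first dermal depth rows.
#' @slot endRow integer matrix (fast x slow), one past the last dermal row.
#' @slot spacing voxel spacing (um).
#' @slot clipped TRUE when the grid was too shallow for the full 1.5 mm.
#'
#' @exportClass DermisSlab
setClass("DermisSlab",
  representation(
    startRow = "matrix",
    endRow = "matrix",
    spacing = "numeric",
    clipped = "logical"
  )
)

setValidity("DermisSlab", function(object) {
  msg <- character()
  if (!identical(dim(object@startRow), dim(object@endRow)))
    msg <- c(msg, "'startRow' and 'endRow' must have identical shape")
  if (any(object@endRow < object@startRow))
    msg <- c(msg, "'endRow' must be >= 'startRow'")
  if (length(msg)) msg else TRUE
})

#' VesselNetwork: segmented dermal vasculature on a coronal MIP
#'
#' Binary vessel mask, its one-pixel-wide skeleton, merged junction points
#' (skeleton pixels of degree >= 3 in 8-connectivity, adjacent junction
#' pixels merged), and per-segment centerline statistics.
#'
#' @slot mask logical matrix (fast x slow), the vessel mask.
#' @slot skeleton logical matrix, one-pixel-wide centerlines.
#' @slot junctions data.frame with columns `junction_id`, `fast`, `slow`
#'   (cluster centroids, pixel units) and `n_pixels`.
#' @slot segments data.frame with columns `segment_id`, `length_px`,
#'   `length_um`, `diameter_um`.
#' @slot segmentLabels integer matrix labelling each skeleton pixel with its
#'   segment id (0 = background or junction pixel).
#' @slot junctionLabels integer matrix labelling junction-cluster pixels.
#' @slot spacing lateral pixel spacing (um).
#' @slot band band the network was derived from.
#'
#' @exportClass VesselNetwork
setClass("VesselNetwork",
  representation(
    mask = "matrix",
    skeleton = "matrix",
    junctions = "data.frame",
    segments = "data.frame",
    segmentLabels = "matrix",
    junctionLabels = "matrix",
    spacing = "numeric",
    band = "character"
  )
)

setValidity("VesselNetwork", function(object) {
  msg <- character()
  if (!identical(dim(object@mask), dim(object@skeleton)))
    msg <- c(msg, "'mask' and 'skeleton' must have identical shape")
  if (any(object@skeleton & !object@mask))
    msg <- c(msg, "skeleton must be a subset of the mask")
  if (length(msg)) msg else TRUE
})
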