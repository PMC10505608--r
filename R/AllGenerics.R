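#' Accessors for RSOM data classes
#'
#' `volData()` returns the raw 3D array of a [VolumeGrid-class],
#' `voxelSpacing()` its per-axis spacing in um, `bandName()` its frequency
#' band, `lowBand()`/`highBand()` the two members of a [BandPair-class],
#' and `bandWeight()` the high-band weighting factor.
#'
#' @param x a `VolumeGrid` or `BandPair`.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))
#' @rdname accessors
#' @export
setGeneric("lowBand", function(x) standardGeneric("lowBand"))
#' @rdname accessors
#' @export
setGeneric("highBand", function(x) standardGeneric("highBand"))
#' @rdname accessors
#' @export
setGeneric("bandWeight", function(x) standardGeneric("bandWeight"))

#' @rdname accessors
setMethod("volData", "VolumeGrid", function(x) x@values)
#' @rdname accessors
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "BandPair", function(x) x@low@spacing)
#' @rdname accessors
setMethod("bandName", "VolumeGrid", function(x) x@band)
#' @rdname accessors
setMethod("lowBand", "BandPair", function(x) x@low)
#' @rdname accessors
setMethod("highBand", "BandPair", function(x) x@high)
#' @rdname accessors
setMethod("bandWeight", "BandPair", function(x) x@weight)

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@values)
  ext <- (d - 1) * object@spacing / 1000
  cat(sprintf(
    "VolumeGrid [%s band]: %d x %d x %d voxels (depth x fast x slow)\n",
    object@band, d[1], d[2], d[3]))
  cat(sprintf("  spacing %g x %g x %g um, extent %.2f x %.2f x %.2f mm\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              ext[1], ext[2], ext[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "BandPair", function(object) {
  d <- dim(object@low@values)
  cat(sprintf("BandPair: %d x %d x %d voxels, high-band weight %.3g\n",
              d[1], d[2], d[3], object@weight))
})

setMethod("show", "LayerBoundaries", function(object) {
  dz <- object@spacing[1]
  w <- mean(object@bottom - object@top) * dz
  cat(sprintf(
    "LayerBoundaries: %d stacks x %d columns, mean EP width %.1f um\n",
    nrow(object@top), ncol(object@top), w))
})

setMethod("show", "DermisSlab", function(object) {
  d <- dim(object@startRow)
  n <- mean(object@endRow - object@startRow)
  cat(sprintf(
    "DermisSlab: %d x %d columns, mean depth extent %.0f um%s\n",
    d[1], d[2], n * object@spacing[1],
    if (object@clipped) " (clipped at grid bottom)" else ""))
})

setMethod("show", "VesselNetwork", function(object) {
  cat(sprintf(
    "VesselNetwork [%s band]: %d mask px, %d segments, %d junctions\n",
    object@band, sum(object@mask), nrow(object@segments),
    nrow(object@junctions)))
})
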