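#' Specify a synthetic vessel
#'
#' A vessel is a piecewise-linear tube given by ordered centerline control
#' points in physical coordinates and a constant diameter. Vessels are
#' rendered into one frequency band, mirroring the band-to-size mapping of
#' the imaging system (large 40-150 um vessels dominate the 10-40 MHz
#' band, small <40 um vessels the 40-120 MHz band).
#'
#' @param points numeric matrix with >= 2 rows and columns
#'   (depth_um, fast_um, slow_um): ordered centerline control points.
#' @param diameter vessel diameter in um (> 0).
#' @param band `"low"` or `"high"`.
#' @param intensity absorbed-energy amplitude (arbitrary units).
#' @return A validated `VesselSpec` list.
#' @export
vesselSpec <- function(points, diameter, band = c("low", "high"),
                       intensity = 1) {
  band <- match.arg(band)
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 3L)
    stop("vessel needs >= 2 control points with (depth, fast, slow) um")
  if (!is.finite(diameter) || diameter <= 0)
    stop("vessel diameter must be > 0")
  structure(list(points = points, diameter = diameter, band = band,
                 intensity = intensity), class = "VesselSpec")
}

#' Specify a skin phantom
#'
#' Defines a two-band synthetic RSOM scene: a bright epidermis slab with
#' sinusoidal ridge texture sitting on a skin surface (constant depth or a
#' function of lateral position), over a dermis containing tubular
#' vessels. Volumes are blurred by an anisotropic Gaussian point-spread
#' function whose default sigmas derive from the system's stated axial and
#' lateral resolutions (4.5 and 18.4 um FWHM), and corrupted by additive
#' zero-mean Gaussian noise.
#'
#' @param gridShape integer triple (depth, fast, slow) voxel counts.
#' @param voxelSpacing um triple, default `c(3, 12, 12)`.
#' @param surfaceDepth skin-surface depth in um: a constant, or a
#'   function `f(fast_um, slow_um)` (vectorized over equal-length inputs).
#' @param epThickness epidermis thickness in um (> 0).
#' @param epIntensity epidermis amplitude (arbitrary units).
#' @param ridgePeriod period of the ridge texture along the fast axis, um.
#' @param ridgeAmplitude fractional intensity modulation of the ridges
#'   (0 disables; cosmetic only, never used by biomarkers).
#' @param vessels list of [vesselSpec()] objects.
#' @param noiseSigma additive Gaussian noise sd (arbitrary units).
#' @param psfSigma um triple of Gaussian PSF sigmas (depth, fast, slow);
#'   default `c(4.5, 18.4, 18.4) / 2.355` (FWHM to sigma).
#' @param seed integer seed; generation is bit-reproducible.
#' @return A validated `PhantomSpec` list.
#' @export
phantomSpec <- function(gridShape, voxelSpacing = c(3, 12, 12),
                        surfaceDepth = 300, epThickness = 105,
                        epIntensity = 1, ridgePeriod = 150,
                        ridgeAmplitude = 0, vessels = list(),
                        noiseSigma = 0,
                        psfSigma = c(4.5, 18.4, 18.4) / 2.355,
                        seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3L || any(gridShape < 3L))
    stop("gridShape must be 3 integers >= 3")
  if (any(voxelSpacing <= 0)) stop("voxel spacing must be positive")
  if (epThickness <= 0) stop("epThickness must be > 0")
  if (!all(vapply(vessels, inherits, logical(1), "VesselSpec")))
    stop("'vessels' must be a list of vesselSpec() objects")
  structure(list(
    gridShape = gridShape, voxelSpacing = as.numeric(voxelSpacing),
    surfaceDepth = surfaceDepth, epThickness = epThickness,
    epIntensity = epIntensity, ridgePeriod = ridgePeriod,
    ridgeAmplitude = ridgeAmplitude, vessels = vessels,
    noiseSigma = noiseSigma, psfSigma = as.numeric(psfSigma),
    seed = as.integer(seed)
  ), class = "PhantomSpec")
}

# Evaluate the surface depth map on the lateral grid (um), as a
# (fast x slow) matrix.
surfaceDepthMatrix <- function(spec) {
  nf <- spec$gridShape[2]; ns <- spec$gridShape[3]
  fx <- (seq_len(nf) - 1) * spec$voxelSpacing[2]
  sy <- (seq_len(ns) - 1) * spec$voxelSpacing[3]
  if (is.function(spec$surfaceDepth)) {
    outer(fx, sy, function(x, y) spec$surfaceDepth(x, y))
  } else {
    matrix(spec$surfaceDepth, nf, ns)
  }
}

# Rasterize one vessel into a logical array: voxel centers within
# diameter/2 of the piecewise-linear centerline.
rasterizeVessel <- function(vessel, gridShape, spacing) {
  mask <- array(FALSE, gridShape)
  r <- vessel$diameter / 2
  ext <- (gridShape - 1) * spacing
  if (any(vessel$points < -1e-9) ||
      any(t(vessel$points) > ext + 1e-9))
    stop("vessel centerline outside the grid extent")
  zc <- (seq_len(gridShape[1]) - 1) * spacing[1]
  xc <- (seq_len(gridShape[2]) - 1) * spacing[2]
  yc <- (seq_len(gridShape[3]) - 1) * spacing[3]
  for (s in seq_len(nrow(vessel$points) - 1L)) {
    p <- vessel$points[s, ]; q <- vessel$points[s + 1L, ]
    lo <- pmin(p, q) - r; hi <- pmax(p, q) + r
    iz <- which(zc >= lo[1] & zc <= hi[1])
    ix <- which(xc >= lo[2] & xc <= hi[2])
    iy <- which(yc >= lo[3] & yc <= hi[3])
    if (!length(iz) || !length(ix) || !length(iy)) next
    g <- expand.grid(z = zc[iz], x = xc[ix], y = yc[iy])
    d <- q - p
    len2 <- sum(d^2)
    if (len2 == 0) {
      dist2 <- (g$z - p[1])^2 + (g$x - p[2])^2 + (g$y - p[3])^2
    } else {
      t <- ((g$z - p[1]) * d[1] + (g$x - p[2]) * d[2] +
              (g$y - p[3]) * d[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      dist2 <- (g$z - (p[1] + t * d[1]))^2 + (g$x - (p[2] + t * d[2]))^2 +
        (g$y - (p[3] + t * d[3]))^2
    }
    inside <- dist2 <= r^2
    if (any(inside)) {
      sub <- as.matrix(expand.grid(z = iz, x = ix, y = iy))[inside, ,
                                                            drop = FALSE]
      mask[sub] <- TRUE
    }
  }
  mask
}

# Branch points of the union centerline graph: control points shared by
# >= 3 incident polyline segments (merged within a 1 um tolerance).
countBranchPoints <- function(vessels, tol = 1) {
  if (!length(vessels)) return(0L)
  pts <- do.call(rbind, lapply(vessels, function(v) v$points))
  key <- apply(round(pts / tol), 1, paste, collapse = "_")
  uk <- unique(key)
  nodeOf <- match(key, uk)
  deg <- integer(length(uk))
  off <- 0L
  for (v in vessels) {
    n <- nrow(v$points)
    for (s in seq_len(n - 1L)) {
      a <- nodeOf[off + s]; b <- nodeOf[off + s + 1L]
      deg[a] <- deg[a] + 1L
      deg[b] <- deg[b] + 1L
    }
    off <- off + n
  }
  sum(deg >= 3L)
}

#' Generate a synthetic two-band skin volume with known ground truth
#'
#' Renders the epidermis slab into both bands and each vessel as a hard
#' cylinder into its own band, then applies the Gaussian PSF blur and
#' additive noise. The returned truth describes the scene *before*
#' blur/noise: epidermis top/bottom surfaces, per-band vessel masks,
#' per-vessel diameter/length, branch-point count, and the analytic total
#' blood volume fraction over the dermis slab (epidermis bottom to 1.5 mm
#' deeper, clipped at the grid bottom).
#'
#' @param spec a [phantomSpec()].
#' @return A list with elements `pair` (a [BandPair-class]) and `truth`
#'   (class `PhantomTruth`): see Details.
#' @export
makeSkinPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  gs <- spec$gridShape; sp <- spec$voxelSpacing
  surf <- surfaceDepthMatrix(spec)          # (fast x slow), um
  epBottom <- surf + spec$epThickness
  zc <- (seq_len(gs[1]) - 1) * sp[1]

  # epidermis slab, half-open [top, bottom), with ridge texture on fast axis
  fx <- (seq_len(gs[2]) - 1) * sp[2]
  ridge <- 1 + spec$ridgeAmplitude * sin(2 * pi * fx / spec$ridgePeriod)
  ep <- array(0, gs)
  for (j in seq_len(gs[2])) {
    amp <- spec$epIntensity * ridge[j]
    for (k in seq_len(gs[3])) {
      inEp <- zc >= surf[j, k] & zc < epBottom[j, k]
      if (any(inEp)) ep[inEp, j, k] <- amp
    }
  }

  vesselMask <- list(low = array(FALSE, gs), high = array(FALSE, gs))
  vols <- list(low = ep, high = ep)
  vtab <- data.frame(vessel_id = integer(), diameter_um = numeric(),
                     length_um = numeric(), band = character(),
                     n_voxels = integer())
  for (i in seq_along(spec$vessels)) {
    v <- spec$vessels[[i]]
    m <- rasterizeVessel(v, gs, sp)
    vesselMask[[v$band]] <- vesselMask[[v$band]] | m
    vols[[v$band]][m] <- pmax(vols[[v$band]][m], v$intensity)
    segLen <- sum(sqrt(rowSums(diff(v$points)^2)))
    vtab <- rbind(vtab, data.frame(
      vessel_id = i, diameter_um = v$diameter, length_um = segLen,
      band = v$band, n_voxels = sum(m)))
  }

  # analytic dermis slab and TBV from the pre-blur rasterization
  dermisRows <- round(1500 / sp[1])
  startRow <- round(epBottom / sp[1]) + 1L   # first row at/below EP bottom
  endRow <- pmin(startRow + dermisRows, gs[1] + 1L)
  slabVox <- 0L; vesselVox <- 0L
  anyVessel <- vesselMask$low | vesselMask$high
  for (j in seq_len(gs[2])) for (k in seq_len(gs[3])) {
    if (startRow[j, k] > gs[1]) next
    rows <- startRow[j, k]:(endRow[j, k] - 1L)
    slabVox <- slabVox + length(rows)
    vesselVox <- vesselVox + sum(anyVessel[rows, j, k])
  }
  tbvTruth <- if (slabVox > 0) 100 * vesselVox / slabVox else 0

  sigmaVox <- spec$psfSigma / sp
  for (b in c("low", "high")) {
    vols[[b]] <- gaussianBlur3d(vols[[b]], sigmaVox)
    if (spec$noiseSigma > 0)
      vols[[b]] <- vols[[b]] + array(stats::rnorm(prod(gs), 0,
                                                  spec$noiseSigma), gs)
  }

  pair <- BandPair(
    VolumeGrid(vols$low, spacing = sp, band = "low"),
    VolumeGrid(vols$high, spacing = sp, band = "high"),
    weight = 1
  )
  truth <- structure(list(
    epTop = surf, epBottom = epBottom,
    vesselMask = vesselMask, vessels = vtab,
    branchPoints = countBranchPoints(spec$vessels),
    tbvPct = tbvTruth, dermisSlabVoxels = slabVox,
    spec = spec
  ), class = "PhantomTruth")
  list(pair = pair, truth = truth)
}

#' Write phantom outputs to a directory
#'
#' Band volumes go out as multi-page TIFF + JSON sidecars through the
#' volume I/O layer; the ground truth as JSON plus per-band mask TIFFs.
#'
#' @param phantom result of [makeSkinPhantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(phantom$pair@low, file.path(dir, "band_low.tif"))
  writeVolume(phantom$pair@high, file.path(dir, "band_high.tif"))
  for (b in c("low", "high")) {
    m <- phantom$truth$vesselMask[[b]]
    writeVolume(VolumeGrid(m * 1, spacing = phantom$pair@low@spacing,
                           band = b),
                file.path(dir, sprintf("truth_mask_%s.tif", b)))
  }
  tr <- phantom$truth
  jsonlite::write_json(list(
    ep_top_um = tr$epTop, ep_bottom_um = tr$epBottom,
    vessels = tr$vessels, branch_points = tr$branchPoints,
    tbv_pct = tr$tbvPct, dermis_slab_voxels = tr$dermisSlabVoxels
  ), file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
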