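# Epidermis segmentation: stack splitting, sagittal MIPs, and the
# graph/dynamic-programming two-boundary search, followed by boundary
# smoothing and the derived epidermis/dermis quantities.

#' Split a volume into stacks along the slow axis
#'
#' The low-band volume is split into four 0.5 mm stacks along the slow
#' scanning axis before layer segmentation. Stacks partition the axis by
#' equal voxel counts; when the count does not divide evenly, the leading
#' stacks take one extra slice (167 slices -> 42, 42, 42, 41). A slow
#' extent other than 2 mm is split proportionally with a warning.
#'
#' @param grid a [VolumeGrid-class].
#' @param nStacks number of stacks (default 4).
#' @return List of `nStacks` [VolumeGrid-class] objects, with attributes
#'   `"stackStart"`/`"stackEnd"` giving the slow-index ranges.
#' @export
splitStacks <- function(grid, nStacks = 4L) {
  ns <- dim(grid@values)[3]
  extent <- ns * grid@spacing[3]
  if (abs(extent - 2000) > 60)           # tolerate discretization slack
    warning(sprintf(
      "slow extent %.2f mm differs from the nominal 2 mm; splitting %d slices proportionally",
      extent / 1000, ns))
  q <- ns %/% nStacks; r <- ns %% nStacks
  sizes <- rep(q, nStacks) + c(rep(1L, r), rep(0L, nStacks - r))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- lapply(seq_len(nStacks), function(i) {
    VolumeGrid(grid@values[, , starts[i]:ends[i], drop = FALSE],
               spacing = grid@spacing, band = grid@band,
               originDepth = grid@originDepth)
  })
  attr(out, "stackStart") <- starts
  attr(out, "stackEnd") <- ends
  out
}

#' Maximum intensity projection of a stack along the slow axis
#'
#' @param stack a [VolumeGrid-class] (one stack).
#' @return A (depth x fast) matrix: per-pixel maximum over slow slices.
#' @export
stackMIP <- function(stack) {
  v <- stack@values
  apply(v, c(1, 2), max)
}

# Column-normalized vertical intensity gradient of a (depth x fast)
# image. polarity +1: dark-above/bright-below transitions score high
# (top boundary); -1: bright-to-dark (bottom boundary).
normalizedGradient <- function(img, polarity = 1) {
  n <- nrow(img)
  grad <- (rbind(img[-1, , drop = FALSE], img[n, , drop = FALSE]) -
             rbind(img[1, , drop = FALSE], img[-n, , drop = FALSE])) / 2
  grad <- polarity * grad
  rng <- apply(grad, 2, range)
  span <- rng[2, ] - rng[1, ]
  g <- sweep(grad, 2, rng[1, ])
  g <- sweep(g, 2, ifelse(span > 0, span, 1), "/")
  g[, span == 0] <- 0
  g
}

# Exact shortest monotone-column path by dynamic programming.
# Nodes carry gain g; a directed edge from row r' (col j-1) to row r
# (col j) with |r - r'| <= jump costs 2 - (g[r',j-1] + g[r,j]) + eps.
# Virtual zero-cost start/end columns make the endpoints free. `allowed`
# masks nodes out of the search region.
dpMinPath <- function(g, jump = 1L, eps = 1e-5, allowed = NULL) {
  n <- nrow(g); m <- ncol(g)
  if (m < 1L) stop("empty image")
  if (is.null(allowed)) allowed <- matrix(TRUE, n, m)
  D <- matrix(Inf, n, m)
  P <- matrix(0L, n, m)
  D[allowed[, 1], 1] <- 0
  if (m > 1) for (j in 2:m) {
    prev <- D[, j - 1] - g[, j - 1]
    best <- rep(Inf, n); arg <- integer(n)
    for (s in (-jump):jump) {
      cand <- if (s == 0) prev else if (s > 0)
        c(prev[-(1:s)], rep(Inf, s)) else
        c(rep(Inf, -s), prev[1:(n + s)])
      # cand[r] = prev[r + s]: predecessor at row r + s
      upd <- cand < best
      best[upd] <- cand[upd]
      arg[upd] <- s
    }
    col <- best + 2 + eps - g[, j]
    col[!allowed[, j]] <- Inf
    D[, j] <- col
    P[, j] <- arg
  }
  endRow <- which.min(D[, m])
  if (!is.finite(D[endRow, m])) return(NULL)
  path <- integer(m)
  path[m] <- endRow
  if (m > 1) for (j in m:2) path[j - 1] <- path[j] + P[path[j], j]
  list(path = path, cost = D[endRow, m])
}

#' Segment the epidermis boundaries on a 2D stack MIP
#'
#' Finds the top (dark-to-bright) and bottom (bright-to-dark) epidermis
#' boundaries of a sagittal (depth x fast) MIP as two exact minimal-cost
#' left-to-right paths through a node-per-pixel graph. Edges connect each
#' pixel to the pixels of the next column within `jumpLimit` rows; the
#' edge cost is `2 - (g(a) + g(b)) + eps` where `g` is the
#' column-normalized vertical gradient with boundary-specific polarity.
#' The bottom path is searched strictly below the found top path (at
#' least `minSeparation` rows deeper).
#'
#' @param image (depth x fast) numeric matrix with >= 3 columns.
#' @param jumpLimit maximum row change between adjacent columns.
#' @param eps small positive edge-cost offset.
#' @param minSeparation minimum top-to-bottom row separation.
#' @return List with `top`, `bottom` (integer row per column), `costTop`,
#'   `costBottom`.
#' @export
segmentEpidermis2d <- function(image, jumpLimit = 1L, eps = 1e-5,
                               minSeparation = 2L) {
  if (ncol(image) < 3L) stop("image must have at least 3 columns")
  gTop <- normalizedGradient(image, polarity = 1)
  top <- dpMinPath(gTop, jump = jumpLimit, eps = eps)
  gBot <- normalizedGradient(image, polarity = -1)
  allowed <- matrix(TRUE, nrow(image), ncol(image))
  for (j in seq_len(ncol(image)))
    allowed[seq_len(min(top$path[j] + minSeparation - 1L, nrow(image))), j] <- FALSE
  bottom <- dpMinPath(gBot, jump = jumpLimit, eps = eps, allowed = allowed)
  if (is.null(bottom))
    stop("no feasible bottom boundary below the top boundary")
  list(top = top$path, bottom = bottom$path,
       costTop = top$cost, costBottom = bottom$cost)
}

#' Smooth and merge per-stack epidermis boundaries
#'
#' Moving-average smoothing of each stack's top and bottom curves along
#' the fast axis; the `bottom >= top` constraint is re-enforced after
#' smoothing by clamping the bottom to the top where violated.
#'
#' @param boundaries list of per-stack results of [segmentEpidermis2d()].
#' @param stackStart,stackEnd slow-index ranges (from [splitStacks()]).
#' @param spacing voxel spacing (um) of the segmented grid.
#' @param window smoothing window in columns (default 11).
#' @return A [LayerBoundaries-class].
#' @export
smoothBoundaries <- function(boundaries, stackStart, stackEnd,
                             spacing = c(3, 12, 12), window = 11L) {
  k <- length(boundaries)
  nf <- length(boundaries[[1]]$top)
  top <- matrix(0, k, nf); bottom <- matrix(0, k, nf)
  for (i in seq_len(k)) {
    top[i, ] <- movingAverage(boundaries[[i]]$top, window)
    bottom[i, ] <- movingAverage(boundaries[[i]]$bottom, window)
  }
  bottom <- pmax(bottom, top)
  new("LayerBoundaries", top = top, bottom = bottom,
      stackStart = as.integer(stackStart), stackEnd = as.integer(stackEnd),
      spacing = as.numeric(spacing))
}

#' Epidermal thickness
#'
#' Mean over the four stacks of the mean per-column boundary width
#' (bottom minus top), converted to um by the depth spacing.
#'
#' @param boundaries a [LayerBoundaries-class].
#' @return Thickness in um.
#' @export
epThickness <- function(boundaries) {
  perStack <- rowMeans(boundaries@bottom - boundaries@top)
  mean(perStack) * boundaries@spacing[1]
}

#' Epidermal signal density
#'
#' Sum of voxel intensity inside the segmented epidermis slab divided by
#' the number of epidermis voxels, over the full scanning region. The
#' per-stack boundaries are applied to every slow slice of their stack;
#' the slab is half-open `[top, bottom)` in (rounded) depth rows.
#'
#' @param grid the segmented [VolumeGrid-class] (flattened volume).
#' @param boundaries a [LayerBoundaries-class].
#' @return Mean intensity per epidermis voxel.
#' @export
epSignalDensity <- function(grid, boundaries) {
  v <- grid@values
  total <- 0; count <- 0
  for (i in seq_len(nrow(boundaries@top))) {
    ks <- boundaries@stackStart[i]:boundaries@stackEnd[i]
    for (j in seq_len(ncol(boundaries@top))) {
      r0 <- round(boundaries@top[i, j])
      r1 <- round(boundaries@bottom[i, j]) - 1L
      if (r1 < r0) next
      rows <- max(1L, r0):min(dim(v)[1], r1)
      total <- total + sum(v[rows, j, ks])
      count <- count + length(rows) * length(ks)
    }
  }
  if (count == 0) stop("empty epidermis region")
  total / count
}

#' Dermis slab below the epidermis
#'
#' Per lateral position, the dermal analysis interval starts at the
#' epidermis bottom boundary and extends 1.5 mm deeper (half-open in
#' depth rows). If the grid is too shallow the slab is clipped at the
#' grid bottom with a warning.
#'
#' The first `guardVoxels` rows below the boundary are excluded from the
#' slab: the axial point-spread function smears the bright epidermis
#' edge over a few depth voxels, and without a guard that tail dominates
#' the top of the dermal interval. The slab end stays at EP bottom +
#' `depthUm`, so the guard trims the analyzed extent by
#' `guardVoxels * dz`.
#'
#' @param boundaries a [LayerBoundaries-class].
#' @param grid the [VolumeGrid-class] the boundaries refer to.
#' @param depthUm slab depth extent in um (default 1500).
#' @param guardVoxels epidermal-bleed guard in depth voxels (default 2,
#'   about three axial PSF sigmas at the nominal resolution).
#' @return A [DermisSlab-class].
#' @export
dermisMask <- function(boundaries, grid, depthUm = 1500, guardVoxels = 2L) {
  d <- dim(grid@values)
  dz <- boundaries@spacing[1]
  nRows <- round(depthUm / dz)
  startRow <- matrix(0L, d[2], d[3])
  for (i in seq_len(nrow(boundaries@bottom))) {
    ks <- boundaries@stackStart[i]:boundaries@stackEnd[i]
    startRow[, ks] <- round(boundaries@bottom[i, ])
  }
  endRow <- startRow + nRows
  startRow <- startRow + as.integer(guardVoxels)
  clipped <- any(endRow > d[1] + 1L)
  if (clipped)
    warning(sprintf(
      "grid too shallow for the full %.1f mm dermis slab; clipping at the grid bottom",
      depthUm / 1000))
  endRow <- pmin(endRow, d[1] + 1L)
  startRow <- pmin(startRow, d[1] + 1L)
  new("DermisSlab", startRow = startRow, endRow = endRow,
      spacing = boundaries@spacing, clipped = clipped)
}

#' Segment the epidermis of a flattened volume
#'
#' Convenience wrapper running the full layer stage: stack splitting,
#' per-stack sagittal MIP, two-boundary dynamic-programming search, and
#' boundary smoothing.
#'
#' @param grid flattened low-band [VolumeGrid-class].
#' @param nStacks number of slow-axis stacks (default 4).
#' @param jumpLimit,eps,minSeparation passed to [segmentEpidermis2d()].
#' @param smoothWindow passed to [smoothBoundaries()].
#' @return A [LayerBoundaries-class].
#' @export
segmentLayers <- function(grid, nStacks = 4L, jumpLimit = 1L, eps = 1e-5,
                          minSeparation = 2L, smoothWindow = 11L) {
  stacks <- splitStacks(grid, nStacks)
  bnds <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    bnds[[i]] <- tryCatch(
      segmentEpidermis2d(stackMIP(stacks[[i]]), jumpLimit = jumpLimit,
                         eps = eps, minSeparation = minSeparation),
      error = function(e) stop("stack ", i, ": ", conditionMessage(e)))
  }
  smoothBoundaries(bnds, attr(stacks, "stackStart"),
                   attr(stacks, "stackEnd"), spacing = grid@spacing,
                   window = smoothWindow)
}

#' Export layer boundaries as CSV
#'
#' @param boundaries a [LayerBoundaries-class].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
writeBoundariesCsv <- function(boundaries, path) {
  dz <- boundaries@spacing[1]
  df <- do.call(rbind, lapply(seq_len(nrow(boundaries@top)), function(i) {
    data.frame(stack = i, column = seq_len(ncol(boundaries@top)),
               top_um = (boundaries@top[i, ] - 1) * dz,
               bottom_um = (boundaries@bottom[i, ] - 1) * dz)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
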