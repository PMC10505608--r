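test_that("stack splitting partitions the slow axis with leading remainder", {
  g <- VolumeGrid(array(seq_len(10 * 8 * 167), c(10, 8, 167)))
  st <- suppressWarnings(splitStacks(g))
  sizes <- vapply(st, function(s) dim(volData(s))[3], numeric(1))
  expect_identical(sizes, c(42, 42, 42, 41))
  # contiguous, non-overlapping, concatenation reproduces the input
  rebuilt <- array(0, c(10, 8, 167))
  starts <- attr(st, "stackStart"); ends <- attr(st, "stackEnd")
  for (i in 1:4) rebuilt[, , starts[i]:ends[i]] <- volData(st[[i]])
  expect_equal(rebuilt, volData(g), ignore_attr = TRUE)
  # an exact 2 mm extent (168 slices at 12 um) splits evenly, no warning
  g2 <- VolumeGrid(array(0, c(4, 4, 168)))
  expect_silent(st2 <- splitStacks(g2))
  expect_true(all(vapply(st2, function(s) dim(volData(s))[3], numeric(1)) == 42))
})

test_that("stack MIP is a pixelwise maximum over slow slices", {
  set.seed(1)
  g <- VolumeGrid(array(runif(6 * 5 * 7), c(6, 5, 7)))
  m <- stackMIP(g)
  for (k in 1:7) expect_true(all(m >= volData(g)[, , k]))
  expect_equal(m, apply(volData(g), c(1, 2), max))
  # single-slice stack -> identity; all-zero -> all-zero
  one <- VolumeGrid(array(runif(6 * 5), c(6, 5, 1)))
  expect_equal(stackMIP(one), volData(one)[, , 1])
  expect_true(all(stackMIP(VolumeGrid(array(0, c(3, 3, 2)))) == 0))
})

test_that("the DP boundary search locates a bright slab", {
  img <- matrix(0, 200, 40)
  img[41:60, ] <- 1
  sg <- segmentEpidermis2d(img)
  expect_true(all(abs(sg$top - 40) <= 1))
  expect_true(all(abs(sg$bottom - 60) <= 1))
})

test_that("DP path cost equals exhaustive enumeration on random 6x6 images", {
  set.seed(123)
  for (rep in 1:25) {
    img <- matrix(runif(36), 6, 6)
    for (pol in c(1, -1)) {
      g <- rsomskin:::normalizedGradient(img, polarity = pol)
      dp <- rsomskin:::dpMinPath(g)
      expect_equal(dp$cost, oracleMinPathCost(img, polarity = pol),
                   tolerance = 1e-12)
    }
  }
})

test_that("a uniform image yields the degenerate flat-path cost", {
  img <- matrix(5, 10, 8)
  sg <- segmentEpidermis2d(img)
  expect_equal(sg$costTop, (8 - 1) * (2 + 1e-5), tolerance = 1e-12)
  expect_error(segmentEpidermis2d(matrix(1, 4, 2)), "3 columns")
})

test_that("boundary smoothing attenuates steps and enforces ordering", {
  n <- 40
  mk <- function(top, bottom) list(top = top, bottom = bottom)
  # single-column step of 4 rows
  stepTop <- c(rep(10, 20), rep(14, 20))
  b <- list(mk(stepTop, stepTop + 30), mk(stepTop, stepTop + 30),
            mk(stepTop, stepTop + 30), mk(stepTop, stepTop + 30))
  sm <- smoothBoundaries(b, c(1, 11, 21, 31), c(10, 20, 30, 40))
  expect_lt(max(abs(diff(sm@top[1, ]))), 1)          # below the jump limit
  # already-smooth lines are unchanged away from the window edges
  flat <- list(mk(rep(12, n), rep(40, n)), mk(rep(12, n), rep(40, n)),
               mk(rep(12, n), rep(40, n)), mk(rep(12, n), rep(40, n)))
  smf <- smoothBoundaries(flat, c(1, 11, 21, 31), c(10, 20, 30, 40))
  expect_equal(smf@top[1, ], rep(12, n))
  # crossing boundaries are clamped to bottom >= top
  crossed <- list(mk(rep(20, n), rep(18, n)), mk(rep(20, n), rep(18, n)),
                  mk(rep(20, n), rep(18, n)), mk(rep(20, n), rep(18, n)))
  smc <- smoothBoundaries(crossed, c(1, 11, 21, 31), c(10, 20, 30, 40))
  expect_true(all(smc@bottom >= smc@top))
})

test_that("EP thickness follows the constant-gap arithmetic", {
  top <- matrix(50, 4, 30); bottom <- matrix(85, 4, 30)   # 35-row gap
  b <- methods::new("LayerBoundaries", top = top, bottom = bottom,
                    stackStart = c(1L, 11L, 21L, 31L),
                    stackEnd = c(10L, 20L, 30L, 40L),
                    spacing = c(3, 12, 12))
  expect_equal(epThickness(b), 105)
})

test_that("EP thickness recovery is accurate and monotone on phantoms", {
  sweep <- c(60, 90, 120, 150)
  rec <- vapply(sweep, function(th) {
    ph <- makeSkinPhantom(smallPhantom(epThickness = th,
                                       gridShape = c(400, 120, 84)))
    flat <- flattenPair(ph$pair)
    suppressWarnings(epThickness(segmentLayers(lowBand(flat))))
  }, numeric(1))
  expect_true(all(abs(rec - sweep) <= 6))            # within 2 depth voxels
  expect_true(all(diff(rec) > 0))
})

test_that("EP signal density is exact for uniform slabs and flatten-invariant", {
  ph <- makeSkinPhantom(smallPhantom(gridShape = c(400, 120, 84),
                                     psfSigma = c(0, 0, 0)))
  flat <- flattenPair(ph$pair)
  bnd <- suppressWarnings(segmentLayers(lowBand(flat)))
  dens <- epSignalDensity(lowBand(flat), bnd)
  expect_equal(dens, 1, tolerance = 0.1)     # uniform EP intensity 1
  # doubling intensities doubles the density
  doubled <- VolumeGrid(2 * volData(lowBand(flat)), band = "low")
  expect_equal(epSignalDensity(doubled, bnd), 2 * dens, tolerance = 1e-12)
  # a tilted phantom, after integer-shift flattening, gives the same
  # density as the flat phantom: the shifts move voxels without touching
  # intensities
  tilt <- function(x, y) 280 + x * (60 / 1428)
  ph2 <- makeSkinPhantom(smallPhantom(gridShape = c(400, 120, 84),
                                      surfaceDepth = tilt))
  flat2 <- flattenPair(ph2$pair)
  bnd2 <- suppressWarnings(segmentLayers(lowBand(flat2)))
  d2 <- epSignalDensity(lowBand(flat2), bnd2)
  expect_equal(d2, dens, tolerance = 0.05)
})

test_that("the dermis slab spans 1.5 mm below the EP bottom", {
  top <- matrix(80, 4, 20); bottom <- matrix(100, 4, 20)  # flat at 300 um
  b <- methods::new("LayerBoundaries", top = top, bottom = bottom,
                    stackStart = c(1L, 6L, 11L, 16L),
                    stackEnd = c(5L, 10L, 15L, 20L),
                    spacing = c(3, 12, 12))
  g <- VolumeGrid(array(0, c(700, 20, 20)))
  slab <- dermisMask(b, g, guardVoxels = 0L)
  expect_true(all(slab@endRow - slab@startRow == 500))
  expect_equal(sum(slab@endRow - slab@startRow), 500 * 20 * 20)
  expect_false(slab@clipped)
  # shallow grid: clipped with a warning
  shallow <- VolumeGrid(array(0, c(400, 20, 20)))   # 1.2 mm total depth
  expect_warning(s2 <- dermisMask(b, shallow, guardVoxels = 0L), "clip")
  expect_true(s2@clipped)
  expect_true(all(s2@endRow <= 401))
})
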