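# synthetic coronal MIP: blurred diagonal band of given perpendicular
# width (pixels), intensity 1
syntheticBand <- function(widthPx, n1 = 120, n2 = 80, blur = 0.65,
                          dir = c(2, 1), through = c(20, 10)) {
  img <- matrix(0, n1, n2)
  nrm <- sqrt(sum(dir^2))
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    d <- abs(-dir[2] * (i - through[1]) + dir[1] * (j - through[2])) / nrm
    if (d <= widthPx / 2) img[i, j] <- 1
  }
  if (blur > 0) {
    k <- rsomskin:::gaussianKernel1d(blur)
    a <- rsomskin:::conv1dAlong(array(img, c(dim(img), 1)), k, 1)
    img <- rsomskin:::conv1dAlong(a, k, 2)[, , 1]
  }
  img
}

test_that("matched-filter kernels are zero-mean and flat images respond 0", {
  ks <- matchedFilterKernels(c(30, 60), 6, 12)
  for (k in ks) expect_lt(abs(sum(k)), 1e-10)
  flat <- matrix(3.7, 40, 40)
  resp <- matchedFilterResponse(flat, c(30, 60), 6, 12)
  expect_lt(max(abs(resp)), 1e-9)
  expect_error(matchedFilterResponse(matrix(1, 4, 4), 300, 4, 12),
               "kernel larger than image")
})

test_that("filter response equals the dense correlation oracle at sampled pixels", {
  set.seed(5)
  img <- matrix(runif(60 * 45), 60, 45)
  kernels <- matchedFilterKernels(c(24, 48), 4, 12)
  resp <- matchedFilterResponse(img, kernels = kernels)
  pix <- cbind(sample(10:50, 5), sample(10:35, 5))
  for (r in 1:5) {
    i <- pix[r, 1]; j <- pix[r, 2]
    direct <- max(vapply(kernels, function(k) oracleCorrAt(img, k, i, j),
                         numeric(1)))
    expect_equal(resp[i, j], direct, tolerance = 1e-9)
  }
})

test_that("the argmax scale tracks the ridge width", {
  for (w in c(30 / 12, 60 / 12)) {
    img <- syntheticBand(w)
    resp <- matchedFilterResponse(img, scalesUm = c(15, 30, 60), 12, 12)
    sc <- attr(resp, "argmaxScale")
    center <- which(img == max(img), arr.ind = TRUE)[1, ]
    expect_equal(sc[center[1], center[2]], w * 12)
  }
})

test_that("vessel mask segmentation is monotone in the threshold", {
  img <- syntheticBand(4)
  resp <- matchedFilterResponse(img)
  m1 <- segmentVessels(resp, threshold = 0.5)
  m2 <- segmentVessels(resp, threshold = 1.0)
  expect_true(all(m1 | !m2))             # higher threshold never grows
  expect_true(all(segmentVessels(matrix(0, 50, 50)) == FALSE))
  # noiseless two-tube image -> two mask components
  two <- syntheticBand(4) + syntheticBand(4, through = c(80, 10))
  r2 <- matchedFilterResponse(two)
  lab <- rsomskin:::labelComponents8(segmentVessels(r2, image = two))
  expect_identical(max(lab), 2L)
})

test_that("skeleton pruning removes only isolated short fragments", {
  m <- matrix(FALSE, 40, 40)
  m[10, 5:35] <- TRUE                    # 31-px line: kept
  m[30, 3:5] <- TRUE                     # 3-px isolated fragment: removed
  sk <- skeletonizeAndPrune(m)
  expect_true(any(sk[10, ]))
  expect_false(any(sk[30, ]))
  expect_gte(sum(sk[10, ]), 29)
  # a short spur attached to a line survives (it is not isolated)
  y <- matrix(FALSE, 40, 40)
  y[20, 5:35] <- TRUE
  y[17:19, 20] <- TRUE                   # 3-px spur
  sky <- skeletonizeAndPrune(y)
  expect_true(any(sky[17:19, 20]))
})

test_that("junction detection matches line/Y/X topology", {
  line <- matrix(FALSE, 30, 30); line[15, 3:27] <- TRUE
  expect_identical(nrow(findJunctions(line)$junctions), 0L)
  y <- matrix(FALSE, 40, 40)
  y[20, 5:20] <- TRUE
  for (s in 1:12) { y[20 - s, 20 + s] <- TRUE; y[20 + s, 20 + s] <- TRUE }
  jy <- findJunctions(y)
  expect_identical(nrow(jy$junctions), 1L)
  # X: two crossing diagonals merge to a single junction cluster
  x <- matrix(FALSE, 41, 41)
  for (s in -15:15) { x[21 + s, 21 + s] <- TRUE; x[21 - s, 21 + s] <- TRUE }
  jx <- findJunctions(x)
  expect_identical(nrow(jx$junctions), 1L)
  # oracle: the flagged pixels all have >= 3 skeleton neighbours
  deg <- rsomskin:::neighborCount8(x)
  expect_true(all(deg[jx$labels > 0] >= 3))
})

test_that("diameters follow the distance-transform oracle and scale with spacing", {
  # rasterized disk, radius 5 px
  disk <- matrix(FALSE, 21, 21)
  for (i in 1:21) for (j in 1:21)
    if ((i - 11)^2 + (j - 11)^2 <= 25) disk[i, j] <- TRUE
  segLab <- matrix(0L, 21, 21); segLab[11, 11] <- 1L
  d <- estimateDiameters(disk, segLab, spacingUm = 1)
  # independent oracle: twice the minimum distance from the centre to any
  # background pixel
  bg <- which(!disk, arr.ind = TRUE)
  oracle <- 2 * sqrt(min((bg[, 1] - 11)^2 + (bg[, 2] - 11)^2))
  expect_equal(d$diameter_um, oracle, tolerance = 1e-6)
  expect_equal(d$diameter_um, 10, tolerance = 1.5)   # pixelization bias
  # 4-px-wide horizontal bar at 12 um spacing
  bar <- matrix(FALSE, 30, 40); bar[14:17, 3:38] <- TRUE
  lab <- matrix(0L, 30, 40); lab[15, 5:35] <- 1L
  d12 <- estimateDiameters(bar, lab, spacingUm = 12)
  expect_equal(d12$diameter_um, 48, tolerance = 12)
  d24 <- estimateDiameters(bar, lab, spacingUm = 24)
  expect_equal(d24$diameter_um, 2 * d12$diameter_um, tolerance = 1e-9)
})

test_that("junction classification respects the 40 um cutoff", {
  mkY <- function(widthPx) {
    y <- matrix(0, 80, 80)
    img <- matrix(FALSE, 80, 80)
    img[40, 5:40] <- TRUE
    for (s in 1:25) { img[40 - s, 40 + s] <- TRUE; img[40 + s, 40 + s] <- TRUE }
    dil <- EBImage::dilate(EBImage::Image(img * 1),
                           EBImage::makeBrush(2 * floor(widthPx / 2) + 1,
                                              "disc"))
    matrix(EBImage::imageData(dil) > 0.5, 80, 80) * 1
  }
  # thin tubes (1 px, ~24 um with blur): one small-vessel junction
  netS <- vesselNetwork(mkY(1), spacingUm = 12, band = "high")
  cS <- countVessels(netS)
  expect_identical(unname(cS), c(1L, 0L, 1L))
  # wide tubes (7 px, 84 um): one large-vessel junction
  netL <- vesselNetwork(mkY(7), spacingUm = 12, band = "low")
  cL <- countVessels(netL)
  expect_identical(unname(cL["lvn"]), 1L)
  expect_identical(unname(cL["tvn"]), 1L)
  # svn + lvn = tvn always, junction-free networks count 0
  line <- syntheticBand(3)
  net0 <- vesselNetwork(line, spacingUm = 12)
  c0 <- countVessels(net0)
  expect_identical(unname(c0["svn"] + c0["lvn"]), unname(c0["tvn"]))
  expect_identical(unname(c0["tvn"]), 0L)
  # optional mode: the unbranched component contributes one count
  cU <- countVessels(net0, countUnbranched = TRUE)
  expect_identical(unname(cU["tvn"]), 1L)
})

test_that("TBV obeys the exact-fraction and scale-invariance identities", {
  vals <- array(0, c(100, 10, 10))
  slab <- methods::new("DermisSlab",
                       startRow = matrix(1L, 10, 10),
                       endRow = matrix(101L, 10, 10),
                       spacing = c(3, 12, 12), clipped = FALSE)
  # 5% of slab voxels at 1.0, rest 0
  set.seed(9)
  hot <- sample(length(vals), 0.05 * length(vals))
  vals[hot] <- 1
  g <- VolumeGrid(vals)
  expect_equal(totalBloodVolume(g, slab), 5, tolerance = 1e-12)
  # global scaling leaves TBV unchanged
  expect_equal(totalBloodVolume(VolumeGrid(vals * 37), slab), 5,
               tolerance = 1e-12)
  # all voxels equal -> all above 20% of max -> 100%
  expect_equal(totalBloodVolume(VolumeGrid(array(2, c(10, 4, 4))),
                                methods::new("DermisSlab",
                                             startRow = matrix(1L, 4, 4),
                                             endRow = matrix(11L, 4, 4),
                                             spacing = c(3, 12, 12),
                                             clipped = FALSE)), 100)
  # empty slab warns and returns 0
  expect_warning(z <- totalBloodVolume(VolumeGrid(array(0, c(10, 4, 4))),
                                       methods::new("DermisSlab",
                                                    startRow = matrix(1L, 4, 4),
                                                    endRow = matrix(11L, 4, 4),
                                                    spacing = c(3, 12, 12),
                                                    clipped = FALSE)),
                 "no signal")
  expect_identical(z, 0)
})

test_that("the diameter histogram bins and conserves counts", {
  h <- diameterHistogram(c(15, 25, 105))
  expect_identical(as.vector(h), c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_identical(attr(h, "excluded"), 0L)
  h2 <- diameterHistogram(numeric(0))
  expect_true(all(h2 == 0L))
  set.seed(2)
  d <- runif(200, 5, 130)
  h3 <- diameterHistogram(d)
  expect_identical(sum(h3) + attr(h3, "excluded"), 200L)
  expect_identical(sum(h3), sum(d >= 10))
  # boundary values land in the right-open bins
  hb <- diameterHistogram(c(10, 20, 100))
  expect_identical(unname(hb[1]), 1L)
  expect_identical(unname(hb[2]), 1L)
  expect_identical(unname(hb[10]), 1L)
})

test_that("dermis MIP is local to the slab", {
  set.seed(4)
  vals <- array(runif(60 * 8 * 6), c(60, 8, 6))
  slab <- methods::new("DermisSlab", startRow = matrix(11L, 8, 6),
                       endRow = matrix(41L, 8, 6),
                       spacing = c(3, 12, 12), clipped = FALSE)
  m <- dermisMIP(VolumeGrid(vals), slab)
  expect_equal(m, apply(vals[11:40, , ], c(2, 3), max))
  # adding voxels below the slab changes nothing
  vals2 <- vals; vals2[45:60, , ] <- 99
  expect_equal(dermisMIP(VolumeGrid(vals2), slab), m)
  # all-zero dermis -> all-zero MIP
  expect_true(all(dermisMIP(VolumeGrid(array(0, c(60, 8, 6))), slab) == 0))
})
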