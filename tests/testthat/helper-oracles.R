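# Shared fixtures and independent brute-force oracles.

# --- phantom fixtures ------------------------------------------------------

# a straight tube crossing most of the lateral field diagonally
straightTube <- function(diameter, band, depthUm = 800, fastMaxUm = 1800,
                         slowMaxUm = 900) {
  vesselSpec(rbind(c(depthUm, 100, 100), c(depthUm, fastMaxUm, slowMaxUm)),
             diameter = diameter, band = band)
}

# standard small phantom grid: 1.92 mm depth x 1.9 mm fast x 1 mm slow
smallPhantom <- function(vessels = list(), epThickness = 105,
                         surfaceDepth = 300, noiseSigma = 0, seed = 7,
                         gridShape = c(640, 160, 84), ...) {
  phantomSpec(gridShape = gridShape, surfaceDepth = surfaceDepth,
              epThickness = epThickness, vessels = vessels,
              noiseSigma = noiseSigma, seed = seed, ...)
}

# --- brute-force oracles ---------------------------------------------------

# point-in-cylinder rasterization of a straight tube, plain triple loop
oracleTubeVoxels <- function(p, q, radius, gridShape, spacing) {
  count <- 0L
  hits <- array(FALSE, gridShape)
  for (i in seq_len(gridShape[1])) for (j in seq_len(gridShape[2]))
    for (k in seq_len(gridShape[3])) {
      x <- c((i - 1) * spacing[1], (j - 1) * spacing[2],
             (k - 1) * spacing[3])
      d <- q - p
      t <- sum((x - p) * d) / sum(d * d)
      t <- min(max(t, 0), 1)
      if (sum((x - (p + t * d))^2) <= radius^2) {
        count <- count + 1L
        hits[i, j, k] <- TRUE
      }
    }
  list(count = count, mask = hits)
}

# exhaustive enumeration of all monotone-column paths (|row step| <= jump)
# under the same edge-cost definition as the DP, with an independently
# computed column-normalized gradient
oracleGradient <- function(img, polarity) {
  n <- nrow(img)
  g <- img * 0
  for (j in seq_len(ncol(img))) {
    grad <- numeric(n)
    for (i in seq_len(n)) {
      up <- img[max(i - 1, 1), j]
      dn <- img[min(i + 1, n), j]
      grad[i] <- polarity * (dn - up) / 2
    }
    lo <- min(grad); hi <- max(grad)
    g[, j] <- if (hi > lo) (grad - lo) / (hi - lo) else 0
  }
  g
}

oracleMinPathCost <- function(img, polarity = 1, jump = 1L, eps = 1e-5) {
  g <- oracleGradient(img, polarity)
  n <- nrow(img); m <- ncol(img)
  best <- Inf
  recurse <- function(path, cost) {
    j <- length(path)
    if (j == m) {
      best <<- min(best, cost)
      return(invisible())
    }
    r <- path[j]
    for (nr in max(1, r - jump):min(n, r + jump)) {
      recurse(c(path, nr), cost + 2 + eps - g[r, j] - g[nr, j + 1])
    }
  }
  for (r0 in seq_len(n)) recurse(r0, 0)
  best
}

# dense direct correlation of one kernel at one pixel (zero padding)
oracleCorrAt <- function(img, kernel, i, j) {
  k1 <- nrow(kernel); k2 <- ncol(kernel)
  h1 <- (k1 - 1) / 2; h2 <- (k2 - 1) / 2
  acc <- 0
  for (u in seq_len(k1)) for (v in seq_len(k2)) {
    ii <- i + u - 1 - h1; jj <- j + v - 1 - h2
    if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img))
      acc <- acc + img[ii, jj] * kernel[u, v]
  }
  acc
}

# exact two-sided Mann-Whitney p by enumerating all rank assignments:
# doubled smaller tail, capped at 1 (the convention of the exact test)
oracleMannWhitneyP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(s) sum(rank(pooled)[s]) - n1 * (n1 + 1) / 2)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# per-position FFT energy fraction of a signal inside a frequency band
oracleBandEnergyFraction <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  sum(P[f > lo & f <= hi]) / sum(P)
}
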