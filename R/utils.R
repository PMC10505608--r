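# Low-level numeric helpers shared across modules.

# 1D Gaussian kernel in voxel units, normalized to sum 1.
gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

# Convolve a 3D array with a 1D kernel along one dimension, zero-padded.
conv1dAlong <- function(x, kernel, dim) {
  k <- length(kernel)
  if (k == 1L) return(x * kernel)
  stopifnot(k %% 2L == 1L)
  h <- (k - 1L) / 2L
  d <- base::dim(x)
  perm <- c(dim, setdiff(seq_along(d), dim))
  xp <- aperm(x, perm)
  dp <- base::dim(xp)
  m <- matrix(xp, nrow = dp[1])
  mp <- rbind(matrix(0, h, ncol(m)), m, matrix(0, h, ncol(m)))
  # stats::filter computes sum(kernel[j] * x[i + h + 1 - j]); a symmetric
  # kernel makes this identical to correlation/convolution.
  f <- stats::filter(mp, kernel, sides = 2)
  res <- matrix(f[(h + 1):(h + dp[1]), , drop = FALSE], nrow = dp[1])
  out <- array(res, dp)
  aperm(out, order(perm))
}

# Separable anisotropic Gaussian blur of a 3D array; sigma in voxels.
gaussianBlur3d <- function(x, sigmaVox) {
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0) x <- conv1dAlong(x, gaussianKernel1d(sigmaVox[ax]), ax)
  }
  x
}

# Centered moving average along a vector, window clipped at the ends so the
# result has the same length (edge windows shrink).
movingAverage <- function(v, window) {
  if (window <= 1L) return(v)
  n <- length(v)
  h <- floor(window / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# 2D median filter with an odd square window; edges use the shrunken window.
medianFilter2d <- function(m, window) {
  if (window <= 1L) return(m)
  h <- floor(window / 2)
  n1 <- nrow(m); n2 <- ncol(m)
  out <- m
  for (i in seq_len(n1)) {
    ri <- max(1L, i - h):min(n1, i + h)
    for (j in seq_len(n2)) {
      rj <- max(1L, j - h):min(n2, j + h)
      out[i, j] <- stats::median(m[ri, rj], na.rm = TRUE)
    }
  }
  out
}

# Same-size 2D cross-correlation with zero padding outside the image,
# computed via FFT. Kernel dimensions must be odd; the kernel is centered.
corr2d <- function(img, kernel) {
  n1 <- nrow(img); n2 <- ncol(img)
  k1 <- nrow(kernel); k2 <- ncol(kernel)
  stopifnot(k1 %% 2L == 1L, k2 %% 2L == 1L)
  if (k1 > n1 || k2 > n2) stop("kernel larger than image")
  N1 <- n1 + k1 - 1L; N2 <- n2 + k2 - 1L
  I <- matrix(0, N1, N2); I[1:n1, 1:n2] <- img
  K <- matrix(0, N1, N2); K[1:k1, 1:k2] <- kernel[k1:1, k2:1]
  C <- Re(stats::fft(stats::fft(I) * stats::fft(K), inverse = TRUE)) / (N1 * N2)
  C[(1:n1) + (k1 - 1L) / 2L, (1:n2) + (k2 - 1L) / 2L, drop = FALSE]
}

# Shift a logical/numeric matrix by (di, dj), filling with `fill`.
shiftMatrix <- function(m, di, dj, fill = 0) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  si <- seq_len(n1) - di; sj <- seq_len(n2) - dj
  oki <- si >= 1 & si <= n1; okj <- sj >= 1 & sj <= n2
  out[oki, okj] <- m[si[oki], sj[okj]]
  out
}

# Count of 8-neighbourhood TRUE pixels for every pixel of a logical matrix.
neighborCount8 <- function(b) {
  s <- matrix(0, nrow(b), ncol(b))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    s <- s + shiftMatrix(b * 1, di, dj)
  }
  s
}

# Rutovitz crossing number: number of 0->1 transitions in the circular
# sequence of 8-neighbours. 1 = endpoint, 2 = line interior, >= 3 = branch
# point. Robust to the double-corner pixels that 8-connected diagonal
# skeletons contain (which have >= 3 neighbours without being branches).
crossingNumber8 <- function(b) {
  p <- list(
    shiftMatrix(b * 1, -1, 0), shiftMatrix(b * 1, -1, 1),
    shiftMatrix(b * 1, 0, 1), shiftMatrix(b * 1, 1, 1),
    shiftMatrix(b * 1, 1, 0), shiftMatrix(b * 1, 1, -1),
    shiftMatrix(b * 1, 0, -1), shiftMatrix(b * 1, -1, -1))
  s <- matrix(0, nrow(b), ncol(b))
  for (i in 1:8) {
    j <- if (i == 8) 1 else i + 1
    s <- s + (p[[i]] == 0 & p[[j]] == 1)
  }
  s
}

# Zhang-Suen topological thinning of a logical matrix to a 1-pixel-wide,
# 8-connected skeleton.
zhangSuenThin <- function(mask) {
  P <- mask * 1
  repeat {
    changed <- FALSE
    for (iter in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shiftMatrix(P, -1, 0); p3 <- shiftMatrix(P, -1, 1)
      p4 <- shiftMatrix(P, 0, 1);  p5 <- shiftMatrix(P, 1, 1)
      p6 <- shiftMatrix(P, 1, 0);  p7 <- shiftMatrix(P, 1, -1)
      p8 <- shiftMatrix(P, 0, -1); p9 <- shiftMatrix(P, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (iter == 1L) {
        cond <- P == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- P == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { P[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  P == 1
}

# 8-connected component labelling of TRUE pixels, via the pixel adjacency
# graph. Returns an integer matrix (0 = background).
labelComponents8 <- function(b) {
  lab <- matrix(0L, nrow(b), ncol(b))
  idx <- which(b)
  if (!length(idx)) return(lab)
  n1 <- nrow(b)
  ij <- arrayInd(idx, dim(b))
  key <- function(i, j) (j - 1L) * n1 + i
  pos <- key(ij[, 1], ij[, 2])
  lookup <- integer(length(b)); lookup[pos] <- seq_along(pos)
  edges <- integer(0)
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                   c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
    ni <- ij[, 1] + off[1]; nj <- ij[, 2] + off[2]
    ok <- ni >= 1 & ni <= n1 & nj >= 1 & nj <= ncol(b)
    ok[ok] <- b[cbind(ni[ok], nj[ok])]
    if (any(ok)) {
      edges <- c(edges, rbind(which(ok), lookup[key(ni[ok], nj[ok])]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(pos), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Otsu threshold on a numeric vector (values > 0 only), 256 histogram bins.
otsuThreshold <- function(v, levels = 256L) {
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) return(Inf)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1] / 2)
  scaled <- (v - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(EBImage::Image(matrix(scaled, nrow = 1)),
                         range = c(0, 1), levels = levels)
  rng[1] + thr01 * (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
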