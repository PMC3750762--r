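# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain formula transcriptions (loops, explicit interpolation
# weights), not by calling the package's samplers.

randomVolume <- function(shape, seed, modality = "other",
                         spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  set.seed(seed)
  VolumeImage(array(sample(0:255, prod(shape), replace = TRUE), shape),
              ImageGrid(shape, spacing, origin), modality)
}

randomRigid <- function(seed, maxAngleDeg = 10, maxTransUm = 2,
                        center = c(0, 0, 0)) {
  set.seed(seed)
  eulerTransform3D(angles = runif(3, -maxAngleDeg, maxAngleDeg) * pi / 180,
                   translation = runif(3, -maxTransUm, maxTransUm),
                   center = center)
}

# Pearson correlation between fixed voxels and trilinearly interpolated
# moving values over the overlap set, transcribed voxel by voxel.
naiveCorrelationOracle <- function(fixed, moving, transform) {
  fg <- imageGrid(fixed)
  mg <- imageGrid(moving)
  fv <- voxelData(fixed)
  mv <- voxelData(moving)
  Li <- solve(linearPart(transform))
  ti <- translationPart(transform)
  shp <- gridShape(fg)
  mshp <- gridShape(mg)
  fs <- numeric(0)
  ms <- numeric(0)
  for (z in seq_len(shp[1]) - 1) for (y in seq_len(shp[2]) - 1)
    for (x in seq_len(shp[3]) - 1) {
      w <- gridOrigin(fg) + c(z, y, x) * gridSpacing(fg)
      mw <- as.vector(Li %*% (w - ti))
      j <- (mw - gridOrigin(mg)) / gridSpacing(mg)
      if (all(j >= 0) && all(j <= mshp - 1)) {
        j0 <- pmin(floor(j), mshp - 2 + (mshp == 1))
        f <- j - j0
        val <- 0
        for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
          wgt <- (if (dz) f[1] else 1 - f[1]) *
                 (if (dy) f[2] else 1 - f[2]) *
                 (if (dx) f[3] else 1 - f[3])
          val <- val + wgt * mv[j0[1] + dz + 1, j0[2] + dy + 1,
                                j0[3] + dx + 1]
        }
        fs <- c(fs, fv[z + 1, y + 1, x + 1])
        ms <- c(ms, val)
      }
    }
  n <- length(fs)
  num <- sum((fs - mean(fs)) * (ms - mean(ms)))
  num / sqrt(sum((fs - mean(fs))^2) * sum((ms - mean(ms))^2))
}

# Brute-force separable-Gaussian 3D convolution with edge replication.
naiveGaussianOracle <- function(arr, kernelSize, sigma) {
  r <- (kernelSize - 1) %/% 2
  off <- -r:r
  w1 <- exp(-off^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  d <- dim(arr)
  out <- array(0, d)
  cl <- function(i, n) min(max(i, 1L), n)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    acc <- 0
    for (a in seq_along(off)) for (b in seq_along(off))
      for (cc in seq_along(off)) {
        acc <- acc + w1[a] * w1[b] * w1[cc] *
          arr[cl(z + off[a], d[1]), cl(y + off[b], d[2]),
              cl(x + off[cc], d[3])]
      }
    out[z, y, x] <- acc
  }
  out
}

# A small smooth structured volume (blurred random blobs) for optimizer
# tests that need non-trivial image content.
structuredVolume <- function(shape = c(24L, 24L, 24L), seed = 1) {
  set.seed(seed)
  arr <- array(0, shape)
  n <- prod(shape)
  arr[sample(n, 25)] <- 255
  v <- VolumeImage(arr, ImageGrid(shape, c(1, 1, 1)))
  gaussianSmooth(v, GaussianSpec(7L, 2.5))
}

lmTestGrid <- function() {
  ImageGrid(c(46L, 120L, 120L), c(15.625, 6.25, 6.25), c(40, 25, 25))
}

rotationErrorDeg <- function(anglesA, anglesB) {
  R <- rotationMatrixZYX(anglesA) %*% t(rotationMatrixZYX(anglesB))
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
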