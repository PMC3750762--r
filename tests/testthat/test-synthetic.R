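test_that("all generators are pure functions of the spec", {
  spec <- PhantomSpec(seed = 13, perSliceJitterSigma = 1)
  a <- makePhantom(spec)
  b <- makePhantom(spec)
  expect_identical(a$density, b$density)
  expect_identical(labelData(a$labels), labelData(b$labels))
  expect_identical(voxelData(simulateMicroCT(a, spec)),
                   voxelData(simulateMicroCT(b, spec)))
  lmA <- simulateLMStack(a, spec)
  lmB <- simulateLMStack(b, spec)
  expect_identical(voxelData(lmA$volume), voxelData(lmB$volume))
  expect_identical(lmA$jitter, lmB$jitter)
  temA <- simulateTEMImage(lmA$volume, spec)
  temB <- simulateTEMImage(lmB$volume, spec)
  expect_identical(temA$image, temB$image)

  # generators leave the caller's RNG stream untouched
  set.seed(99)
  before <- .Random.seed
  invisible(makePhantom(spec))
  expect_identical(.Random.seed, before)
})

test_that("phantom bodies produce the declared densities and volumes", {
  spec <- PhantomSpec(seed = 2)
  ph <- makePhantom(spec)
  for (b in spec@bodies) {
    idx <- round(worldToVoxel(spec@canvas, b$center)) + 1
    expect_gte(ph$density[idx[1], idx[2], idx[3]] + 0.02, b$density)
  }
  # label voxel count of an interior ellipsoid vs its analytic volume
  kidney <- spec@bodies[[3]]
  count <- sum(labelData(ph$labels) == kidney$label)
  analytic <- 4 / 3 * pi * prod(kidney$semiAxes) /
    prod(gridSpacing(spec@canvas))
  expect_lt(abs(count - analytic) / analytic, 0.05)
  expect_identical(labelNames(ph$labels)[["3"]], "kidney")
})

test_that("microCT rendering is bright-on-dark and monotone in density", {
  spec <- PhantomSpec(seed = 3)
  ph <- makePhantom(spec)
  ct <- simulateMicroCT(ph, spec)
  muscle <- spec@bodies[[4]]
  inMuscle <- labelData(ph$labels) == muscle$label
  background <- labelData(ph$labels) == 0L & ph$density < 0.02
  expect_gte(mean(voxelData(ct)[inMuscle]) -
               mean(voxelData(ct)[background]), 50)

  # no blur, no noise: a pure monotone map of density
  spec0 <- PhantomSpec(seed = 3, noiseSigma = c(microct = 0, lm = 0,
                                                tem = 0))
  ct0 <- simulateMicroCT(makePhantom(spec0), spec0, blur = FALSE)
  ord <- order(ph$density)
  expect_true(all(diff(as.vector(voxelData(ct0))[ord]) >= 0))
})

test_that("LM rendering is dark-on-bright with the declared geometry", {
  spec <- PhantomSpec(seed = 4)
  ph <- makePhantom(spec)
  lm <- simulateLMStack(ph, spec)
  # density and LM intensity anticorrelate
  pts <- applyTransform(spec@lmTruth,
                        tricoreg:::canvasPoints(spec@lmGrid))
  dens <- tricoreg:::phantomDensityAt(spec, pts, ph$texture)
  expect_lt(cor(dens, as.numeric(voxelData(lm$volume))), -0.8)
  expect_identical(modality(lm$volume), "lm")
  # with matching declared/true thickness the truth is exactly lmTruth
  expect_identical(linearPart(lm$truth), linearPart(spec@lmTruth))

  # degenerate parameters: identity truth, no jitter, no noise ->
  # LM equals the inverted CT-like rendering up to the contrast map
  spec0 <- PhantomSpec(seed = 4, lmTruth = identityTransform3D(),
                       noiseSigma = c(microct = 0, lm = 0, tem = 0))
  ph0 <- makePhantom(spec0)
  lm0 <- simulateLMStack(ph0, spec0)
  pts0 <- tricoreg:::canvasPoints(spec0@lmGrid)
  dens0 <- tricoreg:::phantomDensityAt(spec0, pts0, ph0$texture)
  expected <- pmin(pmax(round(235 - dens0 * 200), 0), 255)
  expect_lt(max(abs(as.numeric(voxelData(lm0$volume)) - expected)), 1.01)
})

test_that("a declared-thickness error shows up in the effective truth", {
  spec <- PhantomSpec(seed = 5, sliceThickness = c(15.625, 15.625 * 0.95))
  ph <- makePhantom(spec)
  lm <- simulateLMStack(ph, spec)
  ctr <- tricoreg:::gridCenter(spec@lmGrid)
  d <- decomposeAffine3D(lm$truth, ctr)
  expect_equal(d$scales[1], 0.95, tolerance = 1e-12)
  expect_equal(d$scales[2:3], c(1, 1), tolerance = 1e-12)
  expect_identical(transformMode(lm$truth), "rigid_aniso_scale")
})

test_that("TEM rendering downsamples back to its source crop", {
  spec <- PhantomSpec(seed = 6, textureAmp = 0,
                      noiseSigma = c(microct = 0, lm = 0, tem = 0),
                      temTruth = SimilarityTransform2D())
  ph <- makePhantom(spec)
  lm <- simulateLMStack(ph, spec)
  tem <- simulateTEMImage(lm$volume, spec)
  factor <- round(gridSpacing(spec@lmGrid)[2] / spec@temPixelSize)
  roi <- spec@temRoi
  crop <- voxelData(lm$volume)[spec@temSliceIndex + 1L,
                               roi[1] + seq_len(roi[3]),
                               roi[2] + seq_len(roi[4])]
  # block-average the TEM image back to LM resolution
  down <- matrix(0, roi[3], roi[4])
  for (i in seq_len(roi[3])) for (j in seq_len(roi[4])) {
    down[i, j] <- mean(tem$image[(i - 1) * factor + seq_len(factor),
                                 (j - 1) * factor + seq_len(factor)])
  }
  # bilinear upsampling acts like a narrow triangular filter, so block
  # means match the source closely except at body-boundary curvature
  expect_lte(mean(abs(down - crop)), 2)
  expect_lte(max(abs(down - crop)), 32)
  expect_gt(cor(as.vector(down), as.vector(crop)), 0.99)
  expect_error(simulateTEMImage(lm$volume,
                                PhantomSpec(seed = 6,
                                            temRoi = c(100L, 0L, 40L, 40L))),
               "out of bounds")
})

test_that("spec rescaling keeps the phantom geometrically similar", {
  spec <- PhantomSpec(seed = 7)
  small <- scalePhantomSpec(spec, 0.064)
  expect_equal(gridSpacing(small@lmGrid)[1], 1.0)
  expect_equal(gridSpacing(small@canvas), rep(0.8, 3))
  phA <- makePhantom(spec)
  phB <- makePhantom(small)
  # same voxelwise content, different physical size (floating-point
  # rescaling may flip isolated voxels at soft body boundaries)
  expect_equal(phA$density, phB$density, tolerance = 1e-9)
  expect_lt(mean(labelData(phA$labels) != labelData(phB$labels)), 1e-3)
})

test_that("spec validation guards density separation and grids", {
  bodies <- list(
    list(shape = "ellipsoid", center = c(100, 100, 100),
         semiAxes = c(50, 50, 50), density = 0.50, label = 1L, name = "a"),
    list(shape = "ellipsoid", center = c(300, 300, 300),
         semiAxes = c(50, 50, 50), density = 0.55, label = 2L, name = "b"))
  expect_error(PhantomSpec(bodies = bodies), "0.1")
  expect_error(PhantomSpec(bodies = list()), "non-empty")
  expect_error(PhantomSpec(temRoi = c(-1L, 0L, 10L, 10L)), "temRoi")
})
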