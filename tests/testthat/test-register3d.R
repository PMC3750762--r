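test_that("correlation metric hits its analytic anchor points", {
  v <- randomVolume(c(8L, 8L, 8L), seed = 1)
  expect_equal(correlationMetric(v, v, identityTransform3D()), 1,
               tolerance = 1e-12)
  expect_equal(correlationMetric(v, invertIntensities(v),
                                 identityTransform3D()), -1,
               tolerance = 1e-9)
  det <- correlationMetric(v, v, identityTransform3D(), details = TRUE)
  expect_equal(det$overlapFraction, 1)
  expect_identical(det$n, length(voxelData(v)))
})

test_that("metric equals the naive-loop Pearson oracle", {
  for (seed in 1:8) {
    f <- randomVolume(c(8L, 8L, 8L), seed = seed)
    m <- randomVolume(c(8L, 8L, 8L), seed = seed + 100)
    T1 <- randomRigid(seed + 200, maxAngleDeg = 8, maxTransUm = 1.5,
                      center = c(3.5, 3.5, 3.5))
    got <- correlationMetric(f, m, T1, minOverlapFraction = 0.1)
    expect_equal(got, naiveCorrelationOracle(f, m, T1),
                 tolerance = 1e-10)
  }
})

test_that("metric is symmetric under joint inversion and errors cleanly", {
  f <- randomVolume(c(8L, 8L, 8L), seed = 31)
  m <- randomVolume(c(8L, 8L, 8L), seed = 32)
  T1 <- randomRigid(33, maxAngleDeg = 5, maxTransUm = 1,
                    center = c(3.5, 3.5, 3.5))
  expect_equal(correlationMetric(f, m, T1, 0.1),
               correlationMetric(invertIntensities(f),
                                 invertIntensities(m), T1, 0.1),
               tolerance = 1e-12)
  expect_error(correlationMetric(f, m, translationTransform3D(c(0, 0, 50))),
               "insufficient overlap")
  flat <- VolumeImage(array(80, c(8, 8, 8)))
  expect_error(correlationMetric(flat, m, identityTransform3D()),
               "constant")
})

test_that("resampling shifts, fills and preserves labels exactly", {
  v <- randomVolume(c(6L, 7L, 8L), seed = 41)
  idcopy <- resampleVolume(v, imageGrid(v), identityTransform3D())
  expect_identical(voxelData(idcopy)[, , ], voxelData(v)[, , ])

  shifted <- resampleVolume(v, imageGrid(v),
                            translationTransform3D(c(0, 0, 1)))
  expect_identical(voxelData(shifted)[, , 2:8], voxelData(v)[, , 1:7])
  expect_true(all(voxelData(shifted)[, , 1] == 0))

  labs <- array(0L, c(16, 16, 16))
  labs[5:10, 4:9, 6:12] <- 2L
  lv <- LabelVolume(labs, ImageGrid(c(16L, 16L, 16L), c(1, 1, 1)),
                    c("2" = "kidney"))
  moved <- resampleVolume(lv, imageGrid(lv),
                          translationTransform3D(c(2, -1, 3)), "nearest")
  expect_identical(sum(labelData(moved) == 2L), sum(labs == 2L))
  expect_error(resampleVolume(lv, imageGrid(lv), identityTransform3D(),
                              "linear"), "nearest")
})

test_that("registration of a volume with itself stays at identity", {
  v <- structuredVolume(seed = 5)
  res <- affineRegister(v, v, identityTransform3D(),
                        RegistrationConfig(pyramidLevels = 1L, seed = 1))
  expect_gte(finalMetric(res), 0.999)
  d <- decomposeAffine3D(registeredTransform(res),
                         tricoreg:::gridCenter(imageGrid(v)))
  expect_lt(max(abs(d$translation)), 0.1)
  expect_lt(rotationErrorDeg(d$angles, c(0, 0, 0)), 0.05)
  expect_true(hasConverged(res))
  tr <- metricTrace(res)
  expect_true(all(diff(tr$metric[tr$level == 1]) > -1e-12))
  expect_equal(finalMetric(res), tr$metric[nrow(tr)])
})

test_that("phantom ground truth is recovered on the default conditions", {
  spec <- PhantomSpec(seed = 7)
  ph <- makePhantom(spec)
  ct <- simulateMicroCT(ph, spec)
  lm <- simulateLMStack(ph, spec)
  pre <- preprocessForRegistration(lm$volume)
  res <- affineRegister(ct, pre, identityTransform3D(),
                        RegistrationConfig(seed = 1))
  ctr <- tricoreg:::gridCenter(imageGrid(lm$volume))
  dRec <- decomposeAffine3D(registeredTransform(res), ctr)
  dTruth <- decomposeAffine3D(lm$truth, ctr)
  # within one reference-voxel spacing and half a degree
  expect_lt(sqrt(sum((dRec$translation - dTruth$translation)^2)), 12.5)
  expect_lt(rotationErrorDeg(dRec$angles, dTruth$angles), 0.5)
  expect_true(hasConverged(res))
  expect_error(affineRegister(ct, pre,
                              translationTransform3D(c(0, 0, 5000))),
               "insufficient overlap")
})

test_that("transform propagation shares one transform and maps alike", {
  g <- lmTestGrid()
  lmOrig <- randomVolume(c(46L, 120L, 120L), seed = 51,
                         spacing = gridSpacing(g), origin = gridOrigin(g),
                         modality = "lm")
  pre <- preprocessForRegistration(lmOrig)
  T1 <- randomRigid(52, maxAngleDeg = 6, maxTransUm = 10,
                    center = tricoreg:::gridCenter(g))
  out <- propagateTransform(list(lmOrig, pre), T1, g)
  expect_identical(out[[1]]$transform, out[[2]]$transform)
  idx <- rbind(c(0, 0, 0), c(10, 40, 80), c(45, 119, 119))
  w1 <- applyTransform(out[[1]]$transform, voxelToWorld(g, idx))
  w2 <- applyTransform(out[[2]]$transform, voxelToWorld(g, idx))
  expect_identical(w1, w2)   # max deviation exactly 0

  other <- randomVolume(c(46L, 120L, 120L), seed = 53)
  expect_error(propagateTransform(list(other), T1, g), "does not match")

  labs <- array(0L, c(12, 12, 12))
  labs[3:9, 3:9, 3:9] <- 1L
  lv <- LabelVolume(labs, ImageGrid(c(12L, 12L, 12L), c(1, 1, 1)),
                    c("1" = "cube"))
  same <- propagateTransform(list(lv), identityTransform3D(),
                             imageGrid(lv), resampleTo = imageGrid(lv))
  expect_identical(labelData(same[[1]])[, , ], labs[, , ])
})

test_that("propagated labels agree with the analytic shape transform", {
  g <- ImageGrid(c(64L, 64L, 64L), c(1, 1, 1))
  labs <- array(0L, c(64, 64, 64))
  labs[17:48, 13:44, 21:52] <- 1L
  lv <- LabelVolume(labs, g, c("1" = "cuboid"))
  ctr <- tricoreg:::gridCenter(g)
  T1 <- eulerTransform3D(angles = c(5, 0, 0) * pi / 180,
                         translation = c(2.3, -1.7, 3.1), center = ctr)
  moved <- propagateTransform(list(lv), T1, g, resampleTo = g)[[1]]

  # analytic: voxel is inside iff its pre-image falls in the cuboid box
  idx <- cbind(as.vector(slice.index(labs, 1)) - 1,
               as.vector(slice.index(labs, 2)) - 1,
               as.vector(slice.index(labs, 3)) - 1)
  pre <- applyTransform(invert(T1), voxelToWorld(g, idx))
  inside <- pre[, 1] >= 15.5 & pre[, 1] < 47.5 &
            pre[, 2] >= 11.5 & pre[, 2] < 43.5 &
            pre[, 3] >= 19.5 & pre[, 3] < 51.5
  got <- as.vector(labelData(moved)) == 1L
  dice <- 2 * sum(got & inside) / (sum(got) + sum(inside))
  expect_gte(dice, 0.95)
})

test_that("registration is deterministic given its config", {
  v <- structuredVolume(seed = 8)
  m <- resampleVolume(v, imageGrid(v),
                      translationTransform3D(c(1.3, -0.8, 0.5)))
  r1 <- affineRegister(v, m, identityTransform3D(),
                       RegistrationConfig(pyramidLevels = 1L, seed = 3))
  r2 <- affineRegister(v, m, identityTransform3D(),
                       RegistrationConfig(pyramidLevels = 1L, seed = 3))
  expect_identical(linearPart(registeredTransform(r1)),
                   linearPart(registeredTransform(r2)))
  expect_identical(translationPart(registeredTransform(r1)),
                   translationPart(registeredTransform(r2)))
  expect_identical(finalMetric(r1), finalMetric(r2))
})
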