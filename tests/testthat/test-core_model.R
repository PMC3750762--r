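test_that("transform composition behaves like function composition", {
  T1 <- eulerTransform3D(angles = c(0.3, -0.1, 0.2),
                         translation = c(3, -1, 2), scales = 1.4)
  expect_equal(linearPart(compose(identityTransform3D(), T1)),
               linearPart(T1), tolerance = 1e-12)
  expect_equal(translationPart(compose(identityTransform3D(), T1)),
               translationPart(T1), tolerance = 1e-12)

  Ta <- translationTransform3D(c(1, 0, 0))
  Tb <- translationTransform3D(c(0, 2, 0))
  expect_equal(translationPart(compose(Ta, Tb)), c(1, 2, 0))
  expect_equal(translationPart(compose(Tb, Ta)), c(1, 2, 0))

  Rp <- eulerTransform3D(angles = c(pi / 2, 0, 0))
  Rm <- eulerTransform3D(angles = c(-pi / 2, 0, 0))
  I <- compose(Rp, Rm)
  expect_equal(linearPart(I), diag(3), tolerance = 1e-12)
  expect_equal(translationPart(I), c(0, 0, 0), tolerance = 1e-12)

  # action agrees pointwise on random points
  set.seed(4)
  pts <- matrix(runif(30, -50, 50), 10, 3)
  expect_equal(applyTransform(compose(T1, Ta), pts),
               applyTransform(T1, applyTransform(Ta, pts)),
               tolerance = 1e-10)
})

test_that("composition is associative and widens mode correctly", {
  set.seed(11)
  for (i in 1:10) {
    A <- randomRigid(i, center = c(5, 5, 5))
    B <- eulerTransform3D(angles = runif(3, -0.2, 0.2),
                          translation = runif(3, -5, 5),
                          scales = runif(1, 0.8, 1.2))
    C <- eulerTransform3D(angles = runif(3, -0.2, 0.2),
                          translation = runif(3, -5, 5),
                          scales = runif(3, 0.8, 1.2))
    left <- compose(A, compose(B, C))
    right <- compose(compose(A, B), C)
    expect_equal(linearPart(left), linearPart(right), tolerance = 1e-10)
    expect_equal(translationPart(left), translationPart(right),
                 tolerance = 1e-10)
    expect_identical(transformMode(left), "rigid_aniso_scale")
  }
  r2 <- compose(randomRigid(1), randomRigid(2))
  expect_identical(transformMode(r2), "rigid")
})

test_that("inversion is exact and matches the homogeneous-matrix oracle", {
  Tt <- translationTransform3D(c(3, -1, 2))
  expect_equal(translationPart(invert(Tt)), c(-3, 1, -2))
  expect_equal(linearPart(invert(identityTransform3D())), diag(3))

  Ts <- eulerTransform3D(angles = c(30 * pi / 180, 0, 0),
                         translation = c(4, -2, 7), scales = 2)
  H <- rbind(cbind(linearPart(Ts), translationPart(Ts)), c(0, 0, 0, 1))
  Hi <- solve(H)   # brute-force matrix inverse of the same map
  Ti <- invert(Ts)
  expect_equal(linearPart(Ti), Hi[1:3, 1:3], tolerance = 1e-12)
  expect_equal(translationPart(Ti), Hi[1:3, 4], tolerance = 1e-12)
  expect_identical(transformMode(Ti), transformMode(Ts))

  rt <- compose(Ts, invert(Ts))
  expect_equal(linearPart(rt), diag(3), tolerance = 1e-10)
  expect_equal(translationPart(rt), c(0, 0, 0), tolerance = 1e-10)

  bad <- new("AffineTransform3D", linear = diag(3),
             translation = c(0, 0, 0), mode = "rigid",
             convention = "moving_world_to_fixed_world")
  bad@linear[1, 1] <- 0   # bypass validity to hit the runtime guard
  expect_error(invert(bad), "degenerate")
})

test_that("mode invariants are enforced on construction", {
  expect_error(AffineTransform3D(diag(c(1, 2, 1)), mode = "rigid"),
               "orthogonal")
  expect_error(AffineTransform3D(matrix(0, 3, 3)), "singular")
  expect_silent(AffineTransform3D(2 * rotationMatrixZYX(c(0.1, 0, 0)),
                                  mode = "rigid_iso_scale"))
  expect_error(AffineTransform3D(diag(c(1, 2, 3)),
                                 mode = "rigid_iso_scale"), "iso")
})

test_that("voxel-world mapping honors spacing, origin and linearity", {
  lm <- ImageGrid(c(585L, 1200L, 1600L), c(1.5, 0.413, 0.413))
  expect_equal(voxelToWorld(lm, c(1, 1, 1)), c(1.5, 0.413, 0.413))
  expect_equal(voxelToWorld(lm, c(0, 0, 0)), gridOrigin(lm))
  ct <- ImageGrid(c(650L, 638L, 838L), c(1.2, 1.2, 1.2))
  expect_equal(voxelToWorld(ct, c(10, 10, 10)), c(12, 12, 12))
  expect_equal(worldToVoxel(lm, c(3.0, 0.826, 0.413)), c(2, 2, 1))

  g <- ImageGrid(c(5L, 6L, 7L), c(1.7, 0.3, 2.9), c(-4, 2, 0.5))
  set.seed(9)
  pts <- matrix(runif(3000, -100, 100), ncol = 3)
  expect_lt(max(abs(voxelToWorld(g, worldToVoxel(g, pts)) - pts)), 1e-10)

  # affinity: increments are independent of the base point
  a <- matrix(runif(30), 10, 3)
  b <- c(0.3, -2, 7)
  d1 <- voxelToWorld(g, sweep(a, 2, b, "+")) - voxelToWorld(g, a)
  expect_equal(d1, matrix(rep(b * gridSpacing(g), each = 10), 10, 3),
               tolerance = 1e-12)
})

test_that("grid and volume validity rejects malformed objects", {
  expect_error(ImageGrid(c(0L, 4L, 4L), c(1, 1, 1)), "shape")
  expect_error(ImageGrid(c(4L, 4L, 4L), c(0, 1, 1)), "spacing")
  expect_error(VolumeImage(array(-1, c(2, 2, 2))), "0, 255")
  expect_error(VolumeImage(array(0, c(2, 2, 2)), modality = "xyz"),
               "modality")
  expect_error(LabelVolume(array(1L, c(2, 2, 2)),
                           ImageGrid(c(2L, 2L, 2L), c(1, 1, 1))),
               "unnamed")
  expect_silent(LabelVolume(array(1L, c(2, 2, 2)),
                            ImageGrid(c(2L, 2L, 2L), c(1, 1, 1)),
                            c("1" = "kidney")))
})

test_that("the TEM display colormap is a single step at gray 10", {
  cm <- temAlphaColormap()
  op <- opacityTable(cm)
  expect_length(op, 256L)
  expect_identical(op[1:10], rep(0L, 10))      # gray values 0..9
  expect_identical(op[11:256], rep(255L, 246)) # gray values 10..255
  expect_identical(which(diff(op) != 0L), 10L) # exactly one step, at 9->10
  expect_error(AlphaColormap(rep(0L, 255)), "256")
  expect_error(AlphaColormap(rep(300L, 256)), "0, 255")
})

test_that("euler parameterization round-trips through decomposition", {
  set.seed(21)
  for (i in 1:15) {
    ang <- runif(3, -1.2, 1.2)
    tr <- runif(3, -30, 30)
    sc <- runif(3, 0.7, 1.3)
    ctr <- runif(3, -10, 10)
    T1 <- eulerTransform3D(ang, tr, sc, ctr)
    d <- decomposeAffine3D(T1, ctr)
    expect_equal(d$angles, ang, tolerance = 1e-9)
    expect_equal(d$translation, tr, tolerance = 1e-9)
    expect_equal(d$scales, sc, tolerance = 1e-9)
  }
})
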