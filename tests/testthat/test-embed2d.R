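# A registered LM-like stack used across the template tests: the grid of
# semithin sections (1.5 x 0.413 x 0.413 um) with a known rigid transform.
registeredStackFixture <- function(seed = 1) {
  v <- randomVolume(c(8L, 60L, 60L), seed = seed,
                    spacing = c(1.5, 0.413, 0.413), modality = "lm")
  T1 <- eulerTransform3D(angles = c(4, -2, 1) * pi / 180,
                         translation = c(10, 5, -3),
                         center = tricoreg:::gridCenter(imageGrid(v)))
  list(volume = v, transform = T1)
}

test_that("template extraction preserves pixels and 3D placement", {
  fx <- registeredStackFixture()
  tmpl <- extractTemplate(fx$volume, fx$transform, 3L)
  expect_identical(tmpl@pixels, voxelData(fx$volume)[4, , ])
  # pixel (0,0) of a full-slice crop is voxel (slice, 0, 0) in world
  expect_equal(templatePixelToWorld(tmpl, c(0, 0)),
               applyTransform(fx$transform,
                              voxelToWorld(imageGrid(fx$volume),
                                           c(3, 0, 0))),
               tolerance = 1e-12)

  # crop offsets translate to in-plane world offsets of the LM spacing
  crop <- extractTemplate(fx$volume, identityTransform3D(), 3L,
                          c(20L, 10L, 16L, 12L))
  full <- extractTemplate(fx$volume, identityTransform3D(), 3L)
  d <- templatePixelToWorld(crop, c(0, 0)) -
    templatePixelToWorld(full, c(0, 0))
  expect_equal(d, c(0, 20 * 0.413, 10 * 0.413), tolerance = 1e-12)
  # the template plane sits at the slice's z before the 3D transform
  expect_equal(templatePixelToWorld(crop, c(0, 0))[1], 3 * 1.5)

  expect_error(extractTemplate(fx$volume, fx$transform, 99L), "outside")
  expect_error(extractTemplate(fx$volume, fx$transform, 3L,
                               c(50L, 0L, 20L, 10L)), "exceeds")
})

test_that("template resampling matches TEM resolution and keeps world", {
  fx <- registeredStackFixture(seed = 2)
  tmpl <- extractTemplate(fx$volume, fx$transform, 2L,
                          c(5L, 5L, 50L, 50L))
  # resampling to the template's own pixel size is the identity
  same <- resampleTemplate(tmpl, c(0.413, 0.413))
  expect_identical(same@pixels, tmpl@pixels)

  hi <- resampleTemplate(tmpl, 0.025)
  expect_identical(dim(hi@pixels), c(826L, 826L))  # 50 * 0.413 / 0.025
  ctrLo <- (dim(tmpl@pixels) - 1) / 2
  ctrHi <- (dim(hi@pixels) - 1) / 2
  expect_lt(max(abs(templatePixelToWorld(tmpl, ctrLo) -
                      templatePixelToWorld(hi, ctrHi))), 1e-9)
  expect_error(resampleTemplate(tmpl, 0.0001), "64")

  # the printed-size case: a 100 px crop at 0.413 um becomes 1652 px
  # at 0.025 um (supersampling factor 16.52)
  big <- extractTemplate(randomVolume(c(2L, 100L, 100L), seed = 3,
                                      spacing = c(1.5, 0.413, 0.413)),
                         identityTransform3D(), 1L)
  expect_identical(dim(resampleTemplate(big, 0.025)@pixels),
                   c(1652L, 1652L))
})

test_that("2D registration recovers known similarity transforms", {
  fx <- registeredStackFixture(seed = 4)
  sm <- gaussianSmooth(fx$volume, GaussianSpec(c(1L, 5L, 5L),
                                               c(0.8, 1.6, 1.6)))
  tmpl <- extractTemplate(sm, fx$transform, 4L, c(2L, 2L, 56L, 56L))

  # a TEM that IS the template must register at the identity
  res0 <- register2D(tmpl, tmpl@pixels, tmpl@pixelSize, seed = 1)
  t0 <- registeredTransform(res0)
  expect_lt(max(abs(t0@translation)), 0.1)
  expect_lt(abs(t0@angle) * 180 / pi, 0.05)
  expect_gte(finalMetric(res0), 0.999)

  # known shift + rotation, pivot at the TEM center
  truth <- SimilarityTransform2D(angle = 1.5 * pi / 180,
                                 translation = c(3.25, -2.5))
  ctr <- (dim(tmpl@pixels) - 1) / 2
  sa <- tricoreg:::similarityAbout(truth, ctr)
  tem <- .sampleAffine2D(as.numeric(tmpl@pixels), dim(tmpl@pixels),
                         sa$M, sa$offset, dim(tmpl@pixels), 2L, 0)
  tem <- matrix(tricoreg:::roundHalfUp(tem$values), dim(tmpl@pixels)[1])
  res <- register2D(tmpl, tem, tmpl@pixelSize, seed = 1)
  rec <- registeredTransform(res)
  expect_lt(sqrt(sum((rec@translation - truth@translation)^2)), 0.5)
  expect_lt(abs(rec@angle - truth@angle) * 180 / pi, 0.5)

  # pixel-size mismatch is refused with advice to resample
  expect_error(register2D(tmpl, tem, 0.5), "resample")
})

test_that("2D registration recovers a slight isotropic rescale", {
  fx <- registeredStackFixture(seed = 5)
  sm <- gaussianSmooth(fx$volume, GaussianSpec(c(1L, 5L, 5L),
                                               c(0.8, 1.6, 1.6)))
  tmpl <- extractTemplate(sm, fx$transform, 4L, c(2L, 2L, 56L, 56L))
  truth <- SimilarityTransform2D(angle = 0, scale = 1.05,
                                 translation = c(0, 0))
  ctr <- (dim(tmpl@pixels) - 1) / 2
  sa <- tricoreg:::similarityAbout(truth, ctr)
  tem <- .sampleAffine2D(as.numeric(tmpl@pixels), dim(tmpl@pixels),
                         sa$M, sa$offset, dim(tmpl@pixels), 2L, 0)
  tem <- matrix(tricoreg:::roundHalfUp(tem$values), dim(tmpl@pixels)[1])
  res <- register2D(tmpl, tem, tmpl@pixelSize, allowScale = TRUE,
                    scaleBounds = c(0.9, 1.1), seed = 1)
  expect_lt(abs(registeredTransform(res)@scale - 1.05), 0.005)
})

test_that("levels remap follows the printed 10-255 rescale", {
  img <- matrix(c(0, 128, 255, 64), 2, 2)
  out <- levelsRemap(img)
  expect_equal(out[1, 1], 10)   # input 0
  expect_equal(out[1, 2], 255)  # input 255
  expect_equal(out[2, 1], 133)  # round(10 + 128 * 245 / 255)
  full <- levelsRemap(matrix(0:255, 16, 16))
  expect_true(all(diff(as.vector(full)) >= 0))
  expect_gte(min(full), 10)
  expect_lte(max(full), 255)
  # injective up to rounding: at most one collision per adjacent pair
  expect_true(all(diff(as.vector(full)) <= 1))
  expect_error(levelsRemap(img, 200, 100), "floor")
})

test_that("compositing separates exact-zero background from foreground", {
  tem <- levelsRemap(matrix(sample(0:255, 40 * 40, TRUE), 40, 40))
  fx <- registeredStackFixture(seed = 6)
  tmpl <- extractTemplate(fx$volume, fx$transform, 1L,
                          c(5L, 5L, 40L, 40L))
  same <- compositeOnBlack(tem, tmpl, SimilarityTransform2D())
  expect_identical(sum(same == 0), 0L)
  expect_gte(min(same), 10)

  # shifted footprint: uncovered stripe exactly 0, covered part >= floor
  shifted <- compositeOnBlack(tem, tmpl,
                              SimilarityTransform2D(translation = c(0, 20)))
  expect_true(all(shifted[, 1:19] == 0))
  expect_true(all(shifted[, 21:40] >= 10))

  # rigid maps preserve the covered footprint area: the lattice count
  # of the (unclipped) footprint stays within ~2% of the TEM's
  # interpolable area whatever the rotation
  wideStack <- randomVolume(c(2L, 140L, 140L), seed = 8,
                            spacing = c(1.5, 0.413, 0.413))
  wide <- extractTemplate(wideStack, identityTransform3D(), 1L)
  tem100 <- levelsRemap(matrix(sample(0:255, 100 * 100, TRUE), 100, 100))
  area <- 99^2
  for (ang in c(0, 10, 33) * pi / 180) {
    comp <- compositeOnBlack(tem100, wide,
                             SimilarityTransform2D(
                               angle = ang, translation = c(20.3, 20.7)))
    expect_lt(abs(sum(comp > 0) - area) / area, 0.02)
  }

  expect_error(compositeOnBlack(tem, tmpl, SimilarityTransform2D(),
                                canvasShape = c(20, 20)), "smaller")
  expect_error(compositeOnBlack(matrix(0, 40, 40), tmpl,
                                SimilarityTransform2D()), "remapped")
})

test_that("placed slices agree with the template's world geometry", {
  fx <- registeredStackFixture(seed = 7)
  tmpl <- extractTemplate(fx$volume, fx$transform, 2L,
                          c(4L, 6L, 40L, 40L))
  tem <- levelsRemap(tmpl@pixels)
  placed <- placeIn3D(compositeOnBlack(tem, tmpl, SimilarityTransform2D()),
                      SimilarityTransform2D(), tmpl)
  pts <- rbind(c(0, 0), c(10.5, 30.25), c(39, 39))
  expect_lt(max(abs(placedPixelToWorld(placed, pts) -
                      templatePixelToWorld(tmpl, pts))), 1e-10)
  expect_identical(opacityTable(placed@colormap),
                   opacityTable(temAlphaColormap()))
  expect_error(placeIn3D(matrix(0, 10, 10), SimilarityTransform2D(), tmpl),
               "shape")
})
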