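#' @include AllClasses.R AllGenerics.R grid.R transforms.R preprocess.R
NULL

## run `expr` with a locally seeded RNG, leaving the caller's RNG intact
withLocalSeed <- function(seed, expr) {
  seedState <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(seedState))
    assign(".Random.seed", seedState, envir = globalenv())
    else rm(list = ".Random.seed", envir = globalenv()))
  expr
}

defaultBodies <- function() {
  list(
    list(shape = "ellipsoid", center = c(395, 400, 400),
         semiAxes = c(330, 300, 280), density = 0.35, label = 1L,
         name = "mantle"),
    list(shape = "ellipsoid", center = c(430, 330, 330),
         semiAxes = c(140, 110, 100), density = 0.75, label = 2L,
         name = "digestive_gland"),
    list(shape = "ellipsoid", center = c(360, 480, 470),
         semiAxes = c(90, 80, 70), density = 0.55, label = 3L,
         name = "kidney"),
    list(shape = "cuboid", center = c(300, 250, 480),
         semiAxes = c(140, 50, 60), density = 0.95, label = 4L,
         name = "muscle"))
}

#' Recipe for a seeded multimodal phantom
#'
#' Defines a synthetic specimen and the rendering parameters for all
#' three modalities with known ground truth. The default canvas spans
#' about 0.8 mm (the scale of a small juvenile mollusc) at 64^3 voxels of
#' 12.5 um -- desk-scale stand-ins for full-resolution microscopy grids;
#' the default LM grid is anisotropic (finer in-plane than the canvas,
#' coarser across slices), mimicking serial semithin sections.
#'
#' @param seed integer; every generator is a pure function of the spec.
#' @param canvas reference [ImageGrid-class].
#' @param bodies list of body descriptions (see [PhantomSpec-class]);
#'   default: four organ-like bodies with pairwise density contrast
#'   >= 0.1.
#' @param textureAmp band-limited texture amplitude (density units).
#' @param noiseSigma named gray-level noise sigmas per modality.
#' @param lmGrid declared LM [ImageGrid-class].
#' @param lmTruth ground-truth LM-world-to-canvas-world transform;
#'   default: 5 degree in-plane rotation about the LM center plus a
#'   (6, -4, 3) um shift.
#' @param perSliceJitterSigma um; per-slice random-walk drift step.
#' @param sliceThickness numeric(2) (declared, true) slice thickness in
#'   um; unequal values emulate a systematic microtome thickness error.
#' @param temSliceIndex,temRoi,temPixelSize,temTruth TEM recipe: slice,
#'   crop (row0, col0, height, width), pixel size (um) and ground-truth
#'   2D similarity transform.
#' @return a [PhantomSpec-class].
#' @export
PhantomSpec <- function(seed = 1L,
                        canvas = ImageGrid(c(64L, 64L, 64L),
                                           c(12.5, 12.5, 12.5)),
                        bodies = defaultBodies(),
                        textureAmp = 0.12,
                        noiseSigma = c(microct = 3, lm = 3, tem = 2),
                        lmGrid = ImageGrid(c(46L, 120L, 120L),
                                           c(15.625, 6.25, 6.25),
                                           c(40, 25, 25)),
                        lmTruth = NULL,
                        perSliceJitterSigma = 0,
                        sliceThickness = NULL,
                        temSliceIndex = 22L,
                        temRoi = c(40L, 40L, 40L, 40L),
                        temPixelSize = 6.25 / 16,
                        temTruth = SimilarityTransform2D(
                          angle = 2 * pi / 180, scale = 1,
                          translation = c(12.5, -7.25))) {
  if (is.null(lmTruth))
    lmTruth <- eulerTransform3D(angles = c(5, 0, 0) * pi / 180,
                                translation = c(6, -4, 3),
                                center = gridCenter(lmGrid))
  if (is.null(sliceThickness))
    sliceThickness <- rep(lmGrid@spacing[1], 2L)
  new("PhantomSpec", seed = as.integer(seed), canvas = canvas,
      bodies = bodies, textureAmp = textureAmp, noiseSigma = noiseSigma,
      lmGrid = lmGrid, lmTruth = lmTruth,
      perSliceJitterSigma = perSliceJitterSigma,
      sliceThickness = as.numeric(sliceThickness),
      temSliceIndex = as.integer(temSliceIndex),
      temRoi = as.integer(temRoi), temPixelSize = temPixelSize,
      temTruth = temTruth)
}

#' Rescale a phantom spec to a different physical size
#'
#' Returns a geometrically similar phantom with every length (grids,
#' bodies, transforms, jitter, slice thickness, TEM pixel size)
#' multiplied by `factor`. Useful to pose scenarios at a specific
#' physical scale -- e.g. micrometre-thin sections for studying
#' slice-thickness errors -- without changing the specimen's shape or
#' the voxel counts.
#'
#' @param spec a [PhantomSpec-class].
#' @param factor positive scale factor on all lengths.
#' @return the rescaled [PhantomSpec-class].
#' @export
scalePhantomSpec <- function(spec, factor) {
  stopifnot(factor > 0)
  scaleGrid <- function(g) ImageGrid(g@shape, g@spacing * factor,
                                     g@origin * factor)
  out <- spec
  out@canvas <- scaleGrid(spec@canvas)
  out@lmGrid <- scaleGrid(spec@lmGrid)
  out@bodies <- lapply(spec@bodies, function(b) {
    b$center <- b$center * factor
    b$semiAxes <- b$semiAxes * factor
    b
  })
  out@lmTruth <- AffineTransform3D(spec@lmTruth@linear,
                                   spec@lmTruth@translation * factor,
                                   spec@lmTruth@mode)
  out@perSliceJitterSigma <- spec@perSliceJitterSigma * factor
  out@sliceThickness <- spec@sliceThickness * factor
  out@temPixelSize <- spec@temPixelSize * factor
  out
}

## soft indicator of a body at world points: 1 well inside, 0 outside,
## linear ramp of half-width `edge` (relative units) across the boundary
bodyWeight <- function(body, points, edge = 0.08) {
  d <- sweep(points, 2L, body$center)
  d <- sweep(d, 2L, body$semiAxes, "/")
  r <- if (identical(body$shape, "cuboid")) {
    pmax(abs(d[, 1]), abs(d[, 2]), abs(d[, 3]))
  } else {
    sqrt(rowSums(d^2))
  }
  pmin(pmax((1 + edge - r) / (2 * edge), 0), 1)
}

## trilinear interpolation of a (z, y, x) array at fractional 0-based
## indices, edge-replicated; vectorized over scattered points
trilinearAt <- function(arr, idx) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 0), n - 1)
  z <- cl(idx[, 1], d[1]); y <- cl(idx[, 2], d[2]); x <- cl(idx[, 3], d[3])
  z0 <- pmin(floor(z), d[1] - 2 + (d[1] == 1))
  y0 <- pmin(floor(y), d[2] - 2 + (d[2] == 1))
  x0 <- pmin(floor(x), d[3] - 2 + (d[3] == 1))
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  at <- function(dz, dy, dx)
    arr[cbind(z0 + dz + 1, y0 + dy + 1, x0 + dx + 1)]
  (1 - fx) * ((1 - fy) * ((1 - fz) * at(0, 0, 0) + fz * at(1, 0, 0)) +
              fy * ((1 - fz) * at(0, 1, 0) + fz * at(1, 1, 0))) +
    fx * ((1 - fy) * ((1 - fz) * at(0, 0, 1) + fz * at(1, 0, 1)) +
          fy * ((1 - fz) * at(0, 1, 1) + fz * at(1, 1, 1)))
}

## continuous phantom density (and optionally labels) at world points;
## texture is the seeded band-limited field on the canvas grid
phantomDensityAt <- function(spec, points, texture = NULL,
                             withLabels = FALSE) {
  contrib <- vapply(spec@bodies, bodyWeight, numeric(nrow(points)),
                    points = points)
  if (is.null(dim(contrib))) contrib <- matrix(contrib, nrow = 1L)
  dens <- vapply(spec@bodies, function(b) b$density, numeric(1))
  total <- as.vector(contrib %*% dens)
  if (!is.null(texture)) {
    idx <- worldToVoxel(spec@canvas, points)
    total <- total + trilinearAt(texture, idx)
  }
  total <- pmin(pmax(total, 0), 1)
  if (!withLabels) return(total)
  # a point belongs to the densest body whose soft boundary it is inside
  # of (weight > 1/2); overlaps resolve to the denser organ
  eligible <- sweep(contrib > 0.5, 2L, dens, "*")
  best <- max.col(eligible, ties.method = "last")
  inside <- eligible[cbind(seq_along(best), best)] > 0
  labs <- vapply(spec@bodies, function(b) as.integer(b$label), integer(1))
  labels <- ifelse(inside, labs[best], 0L)
  list(density = total, labels = labels)
}

## all canvas voxel centers as an n x 3 world matrix (z fastest, matching
## R array linearization)
canvasPoints <- function(grid) {
  shp <- grid@shape
  idx <- cbind(rep(seq_len(shp[1]) - 1, times = shp[2] * shp[3]),
               rep(rep(seq_len(shp[2]) - 1, each = shp[1]),
                   times = shp[3]),
               rep(seq_len(shp[3]) - 1, each = shp[1] * shp[2]))
  voxelToWorld(grid, idx)
}

## seeded band-limited texture on the canvas grid: smoothed white noise
## rescaled to +/- textureAmp
makeTexture <- function(spec) {
  shp <- spec@canvas@shape
  withLocalSeed(spec@seed, {
    noise <- array(stats::rnorm(prod(shp)), shp)
    k <- gaussianKernel1D(5L, 1.5)
    for (axis in 1:3) noise <- convolveAxis(noise, k, axis)
    noise / max(abs(noise)) * spec@textureAmp
  })
}

#' Generate the phantom density field and label volume
#'
#' Evaluates the bodies (smooth-edged ellipsoids/cuboids whose densities
#' add, clipped to \[0, 1\]) plus a seeded band-limited texture on the
#' canvas grid. Labels mark body membership (strongest contributor wins
#' where bodies overlap). Deterministic per seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `density` (numeric array in \[0, 1\]), `labels`
#'   (a [LabelVolume-class]) and `texture` (the texture field, reused by
#'   the modality simulators).
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  texture <- makeTexture(spec)
  pts <- canvasPoints(spec@canvas)
  res <- phantomDensityAt(spec, pts, texture, withLabels = TRUE)
  names <- vapply(spec@bodies, function(b) b$name, character(1))
  ids <- vapply(spec@bodies, function(b) as.character(b$label), character(1))
  labelNames <- stats::setNames(names, ids)[!duplicated(ids)]
  list(density = array(res$density, spec@canvas@shape),
       labels = LabelVolume(array(res$labels, spec@canvas@shape),
                            spec@canvas, labelNames),
       texture = texture)
}

#' Render the microCT modality of a phantom
#'
#' Bright specimen on a near-black background: intensity increases
#' monotonically with density, followed by a light Gaussian blur and
#' seeded Gaussian read noise. This volume plays the role of the
#' geometrically undistorted reference.
#'
#' @param phantom output of [makePhantom()].
#' @param spec the [PhantomSpec-class].
#' @param blur apply the 3-voxel Gaussian blur (disable to expose the
#'   pure monotone density map).
#' @return a [VolumeImage-class] on the canvas grid, modality
#'   `"microct"`.
#' @export
simulateMicroCT <- function(phantom, spec, blur = TRUE) {
  v <- 8 + phantom$density * 220
  if (blur) {
    k <- gaussianKernel1D(3L, 0.8)
    for (axis in 1:3) v <- convolveAxis(v, k, axis)
  }
  sigma <- spec@noiseSigma[["microct"]]
  if (sigma > 0)
    v <- v + withLocalSeed(spec@seed + 1L,
                           array(stats::rnorm(length(v), 0, sigma), dim(v)))
  VolumeImage(array(pmin(pmax(roundHalfUp(v), 0), 255), dim(v)),
              spec@canvas, "microct")
}

#' Render the LM serial-section stack of a phantom
#'
#' Samples the phantom through the inverse of the ground-truth transform
#' onto the (declared) LM grid with dark-specimen-on-bright-background
#' contrast. Two optional imperfections are modelled: a mean-removed
#' random-walk in-plane drift per slice (sequential section alignment
#' accumulates drift; global pre-alignment removes its mean, leaving the
#' largest residuals at the stack ends) and a mismatch between the
#' declared and the true slice thickness (a systematic microtome error
#' that only an anisotropic z scale can undo).
#'
#' @param phantom output of [makePhantom()].
#' @param spec the [PhantomSpec-class].
#' @return list with `volume` (the LM [VolumeImage-class] on the declared
#'   grid), `truth` (the effective ground-truth
#'   [AffineTransform3D-class] from declared LM world to canvas world,
#'   including the thickness-error scale) and `jitter` (the per-slice
#'   (y, x) drift actually applied, um).
#' @export
simulateLMStack <- function(phantom, spec) {
  g <- spec@lmGrid
  shp <- g@shape
  thDecl <- spec@sliceThickness[1]
  thTrue <- spec@sliceThickness[2]
  jitter <- matrix(0, shp[1], 2)
  if (spec@perSliceJitterSigma > 0) {
    jitter <- withLocalSeed(spec@seed + 2L, {
      steps <- matrix(stats::rnorm(2L * shp[1], 0,
                                   spec@perSliceJitterSigma), ncol = 2)
      walk <- apply(steps, 2L, cumsum)
      sweep(walk, 2L, colMeans(walk))
    })
  }
  texture <- phantom$texture
  vox <- array(0, shp)
  for (k in seq_len(shp[1])) {
    yy <- rep(g@origin[2] + (seq_len(shp[2]) - 1) * g@spacing[2],
              times = shp[3]) + jitter[k, 1]
    xx <- rep(g@origin[3] + (seq_len(shp[3]) - 1) * g@spacing[3],
              each = shp[2]) + jitter[k, 2]
    zz <- rep(g@origin[1] + (k - 1) * thTrue, shp[2] * shp[3])
    pts <- applyTransform(spec@lmTruth, cbind(zz, yy, xx))
    vox[k, , ] <- phantomDensityAt(spec, pts, texture)
  }
  v <- 235 - vox * 200
  sigma <- spec@noiseSigma[["lm"]]
  if (sigma > 0)
    v <- v + withLocalSeed(spec@seed + 3L,
                           array(stats::rnorm(length(v), 0, sigma), dim(v)))
  ratio <- thTrue / thDecl
  scaleZ <- AffineTransform3D(diag(c(ratio, 1, 1)),
                              c(g@origin[1] * (1 - ratio), 0, 0),
                              if (ratio == 1) "rigid" else
                                "rigid_aniso_scale")
  truth <- if (ratio == 1) spec@lmTruth else compose(spec@lmTruth, scaleZ)
  list(volume = VolumeImage(array(pmin(pmax(roundHalfUp(v), 0), 255),
                                  shp), g, "lm"),
       truth = truth, jitter = jitter)
}

#' Segmentation labels on the LM grid
#'
#' Evaluates body membership at exactly the positions the LM stack was
#' sampled at (including per-slice jitter and the true slice thickness),
#' yielding the label volume a manual segmentation of those sections
#' would produce. Shares the LM stack's declared grid, so it can be
#' carried along by [propagateTransform()] as a companion.
#'
#' @param phantom output of [makePhantom()] (unused content-wise; kept
#'   for signature symmetry with the other simulators).
#' @param spec the [PhantomSpec-class].
#' @param jitter the per-slice jitter actually applied to the LM stack
#'   (from [simulateLMStack()]); default none.
#' @return a [LabelVolume-class] on the declared LM grid.
#' @export
simulateLMLabels <- function(phantom, spec,
                             jitter = matrix(0, spec@lmGrid@shape[1], 2)) {
  g <- spec@lmGrid
  shp <- g@shape
  thTrue <- spec@sliceThickness[2]
  labels <- array(0L, shp)
  for (k in seq_len(shp[1])) {
    yy <- rep(g@origin[2] + (seq_len(shp[2]) - 1) * g@spacing[2],
              times = shp[3]) + jitter[k, 1]
    xx <- rep(g@origin[3] + (seq_len(shp[3]) - 1) * g@spacing[3],
              each = shp[2]) + jitter[k, 2]
    zz <- rep(g@origin[1] + (k - 1) * thTrue, shp[2] * shp[3])
    pts <- applyTransform(spec@lmTruth, cbind(zz, yy, xx))
    labels[k, , ] <- phantomDensityAt(spec, pts, NULL,
                                      withLabels = TRUE)$labels
  }
  names <- vapply(spec@bodies, function(b) b$name, character(1))
  ids <- vapply(spec@bodies, function(b) as.character(b$label), character(1))
  LabelVolume(labels, g, stats::setNames(names, ids)[!duplicated(ids)])
}

#' Residual displacement field of a registered jittered stack
#'
#' A stack-to-stack affine registration cannot compensate misalignments
#' within the stack (per-slice drift); it can only fit one global map.
#' This helper quantifies what remains: for every LM voxel it compares
#' where the recovered transform places it against where its content
#' truly came from (the ground-truth transform applied to the
#' jitter-shifted sampling position), and summarizes the residual norm in
#' the innermost and outermost quintile of distance from the specimen
#' center. With drift-like jitter the residuals concentrate peripherally.
#'
#' @param spec the [PhantomSpec-class] the stack was generated from.
#' @param lmSim the list returned by [simulateLMStack()].
#' @param transform the recovered [AffineTransform3D-class].
#' @return list with `coreMean` and `shellMean` (um; mean residual in the
#'   inner/outer 20% by distance from the stack center) and `residuals`
#'   (per-voxel norms, um).
#' @export
sliceJitterResiduals <- function(spec, lmSim, transform) {
  g <- spec@lmGrid
  shp <- g@shape
  idx <- cbind(rep(seq_len(shp[1]) - 1, times = shp[2] * shp[3]),
               rep(rep(seq_len(shp[2]) - 1, each = shp[1]),
                   times = shp[3]),
               rep(seq_len(shp[3]) - 1, each = shp[1] * shp[2]))
  declared <- voxelToWorld(g, idx)
  thTrue <- spec@sliceThickness[2]
  sliceK <- idx[, 1] + 1L
  truePts <- cbind(g@origin[1] + idx[, 1] * thTrue,
                   declared[, 2] + lmSim$jitter[sliceK, 1],
                   declared[, 3] + lmSim$jitter[sliceK, 2])
  target <- applyTransform(spec@lmTruth, truePts)
  placed <- applyTransform(transform, declared)
  resid <- sqrt(rowSums((placed - target)^2))
  ctr <- gridCenter(g)
  dist <- sqrt(rowSums(sweep(declared, 2L, ctr)^2))
  q <- stats::quantile(dist, c(0.2, 0.8))
  list(coreMean = mean(resid[dist <= q[1]]),
       shellMean = mean(resid[dist >= q[2]]),
       residuals = resid)
}

#' Render a TEM image of one LM slice
#'
#' Crops the chosen slice of the simulated LM stack to the TEM region of
#' interest, upsamples it to the TEM pixel size (edge-anchored bilinear,
#' like [resampleTemplate()]), adds seeded sub-LM-resolution texture and
#' noise, and transforms the result by the ground-truth 2D similarity
#' transform (pivot: image center).
#'
#' @param lmStack the LM [VolumeImage-class] from [simulateLMStack()].
#' @param spec the [PhantomSpec-class].
#' @return list with `image` (numeric matrix of 8-bit gray values),
#'   `truth` (the [SimilarityTransform2D-class] mapping TEM pixels to
#'   template pixels) and `pixelSize` (um).
#' @export
simulateTEMImage <- function(lmStack, spec) {
  shp <- lmStack@grid@shape
  roi <- spec@temRoi
  if (spec@temSliceIndex < 0L || spec@temSliceIndex >= shp[1])
    stop("temSliceIndex outside the LM stack")
  if (any(roi[1:2] < 0L) || roi[1] + roi[3] > shp[2] ||
      roi[2] + roi[4] > shp[3])
    stop("temRoi out of bounds for the LM slice")
  crop <- lmStack@voxels[spec@temSliceIndex + 1L,
                         roi[1] + seq_len(roi[3]),
                         roi[2] + seq_len(roi[4]), drop = TRUE]
  crop <- matrix(crop, roi[3], roi[4])
  inPlane <- lmStack@grid@spacing[2:3]
  target <- rep(spec@temPixelSize, length.out = 2L)
  newDim <- as.integer(round(dim(crop) * inPlane / target))
  ratio <- target / inPlane
  up <- .sampleAffine2D(as.numeric(crop), dim(crop), diag(ratio),
                        ratio * 0.5 - 0.5, newDim, 2L, 0)
  up <- matrix(up$values, newDim[1], newDim[2])
  # pull the upsampled content through the ground-truth transform so that
  # registering the TEM image back to the template recovers it
  ctr <- (newDim - 1) / 2
  sa <- similarityAbout(spec@temTruth, ctr)
  res <- .sampleAffine2D(as.numeric(up), newDim, sa$M, sa$offset,
                         newDim, 2L, 0)
  img <- matrix(res$values, newDim[1], newDim[2])
  sigma <- spec@noiseSigma[["tem"]]
  if (spec@textureAmp > 0 || sigma > 0) {
    img <- img + withLocalSeed(spec@seed + 4L, {
      fine <- matrix(stats::rnorm(prod(newDim)), newDim[1], newDim[2])
      k <- gaussianKernel1D(3L, 0.8)
      fine <- apply(fine, 2L, stats::filter, filter = k, sides = 2)
      fine[is.na(fine)] <- 0
      fine / max(abs(fine), 1e-12) * spec@textureAmp * 40 +
        if (sigma > 0) matrix(stats::rnorm(prod(newDim), 0, sigma),
                              newDim[1], newDim[2]) else 0
    })
  }
  list(image = pmin(pmax(roundHalfUp(img), 0), 255),
       truth = spec@temTruth, pixelSize = target)
}
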