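#' @include AllClasses.R AllGenerics.R grid.R transforms.R colormap.R
NULL

## Template pixel (i, j) (0-based, center convention) sits at continuous
## source-slice voxel coordinates
##   row = row0 - 0.5 + (i + 0.5) * pixelRow / spacingRow
##   col = col0 - 0.5 + (j + 0.5) * pixelCol / spacingCol
## i.e. the crop is anchored at the OUTER EDGE of voxel (row0, col0), so
## the same physical point keeps the same world coordinate across
## resampling to a different pixel size. At extraction (pixel size ==
## spacing) this reduces to row = row0 + i.
templateVoxelCoords <- function(template, pixels) {
  sp <- template@sourceGrid@spacing
  row <- template@cropOffset[1] - 0.5 +
    (pixels[, 1] + 0.5) * template@pixelSize[1] / sp[2]
  col <- template@cropOffset[2] - 0.5 +
    (pixels[, 2] + 0.5) * template@pixelSize[2] / sp[3]
  cbind(rep(as.numeric(template@sliceIndex), nrow(pixels)), row, col)
}

#' World coordinates of template pixels
#'
#' Maps template pixel coordinates (0-based (row, col), possibly
#' fractional) through the crop geometry, the source grid and the
#' registered stack's transform to 3D world coordinates in micrometres.
#'
#' @param template a [SliceTemplate-class].
#' @param pixels numeric(2) or an n x 2 matrix of pixel coordinates.
#' @return world coordinates (n x 3 or length 3).
#' @export
templatePixelToWorld <- function(template, pixels) {
  vec <- !is.matrix(pixels)
  if (vec) pixels <- matrix(pixels, 1L)
  w <- applyTransform(template@sourceTransform,
                      voxelToWorld(template@sourceGrid,
                                   templateVoxelCoords(template, pixels)))
  if (vec) as.vector(w) else w
}

## analytic pixel -> world map of a template: world = L %*% (i, j) + o
templatePixelMap <- function(template) {
  o <- templatePixelToWorld(template, c(0, 0))
  L <- cbind(templatePixelToWorld(template, c(1, 0)) - o,
             templatePixelToWorld(template, c(0, 1)) - o)
  list(linear = L, origin = o)
}

#' Extract a placement-aware template from a registered LM stack
#'
#' Isolates one slice of the registered stack and crops it to a region
#' of interest, keeping every detail needed to map template pixels back
#' to 3D world coordinates (the stack's transform travels with the
#' crop). The result is the fixed image for TEM registration.
#'
#' @param volume the registered LM [VolumeImage-class].
#' @param transform the stack's registered [AffineTransform3D-class].
#' @param sliceIndex 0-based slice index.
#' @param roi integer(4) crop `(row0, col0, height, width)` in slice
#'   voxels, 0-based; defaults to the full slice.
#' @return a [SliceTemplate-class].
#' @export
extractTemplate <- function(volume, transform, sliceIndex,
                            roi = NULL) {
  shp <- volume@grid@shape
  if (sliceIndex < 0 || sliceIndex >= shp[1])
    stop(sprintf("sliceIndex %d outside the stack (0..%d)", sliceIndex,
                 shp[1] - 1L))
  if (is.null(roi)) roi <- c(0L, 0L, shp[2], shp[3])
  roi <- as.integer(roi)
  over <- c(roi[1] + roi[3] - shp[2], roi[2] + roi[4] - shp[3])
  if (any(roi[1:2] < 0L) || any(over > 0L))
    stop(sprintf(
      "roi exceeds the %dx%d slice by (%d, %d) voxels at the far edge",
      shp[2], shp[3], max(over[1], 0L), max(over[2], 0L)))
  px <- volume@voxels[sliceIndex + 1L,
                      roi[1] + seq_len(roi[3]),
                      roi[2] + seq_len(roi[4]), drop = TRUE]
  new("SliceTemplate", pixels = matrix(px, roi[3], roi[4]),
      pixelSize = volume@grid@spacing[2:3],
      sliceIndex = as.integer(sliceIndex),
      cropOffset = as.numeric(roi[1:2]),
      sourceTransform = transform, sourceGrid = volume@grid)
}

#' Resample a template to a target pixel size
#'
#' Increases (or decreases) the template's resolution to match a TEM
#' image's pixel size, by bilinear interpolation with edge replication.
#' The output pixel count per axis is `round(extent / targetPixelSize)`
#' and the world coordinate of any material point is preserved: the 3D
#' placement fields are restored onto the resampled template.
#'
#' @param template a [SliceTemplate-class].
#' @param targetPixelSize numeric, recycled to (row, col), micrometres.
#' @return the resampled [SliceTemplate-class].
#' @export
resampleTemplate <- function(template, targetPixelSize) {
  target <- rep(as.numeric(targetPixelSize), length.out = 2L)
  if (any(target <= 0)) stop("targetPixelSize must be positive")
  factor <- template@pixelSize / target
  if (any(factor > 64))
    stop(sprintf(
      "upsampling factor %.1f exceeds 64; crop a smaller ROI first",
      max(factor)))
  oldDim <- dim(template@pixels)
  extent <- oldDim * template@pixelSize
  newDim <- as.integer(round(extent / target))
  ratio <- target / template@pixelSize
  A <- diag(ratio)
  b <- ratio * 0.5 - 0.5
  res <- .sampleAffine2D(as.numeric(template@pixels), oldDim, A, b,
                         newDim, 2L, 0)
  out <- template
  out@pixels <- matrix(roundHalfUp(res$values), newDim[1], newDim[2])
  out@pixelSize <- target
  out
}

## mean-pool a 2D image by factor 2 (trailing odd row/col dropped)
meanPool2D <- function(img) {
  nr <- nrow(img) %/% 2L
  nc <- ncol(img) %/% 2L
  i1 <- seq_len(nr) * 2L - 1L
  j1 <- seq_len(nc) * 2L - 1L
  (img[i1, j1, drop = FALSE] + img[i1 + 1L, j1, drop = FALSE] +
     img[i1, j1 + 1L, drop = FALSE] + img[i1 + 1L, j1 + 1L, drop = FALSE]) / 4
}

## 2D correlation between a fixed image and a similarity-transformed
## moving image, in pooled coordinates (poolFactor f, pooled-pixel center
## offset h = (f-1)/2); transform parameters stay in original pixels
correlation2D <- function(fixedImg, movingImg, t2d, movingCenter,
                          poolFactor, minOverlapFraction) {
  M <- similarityMatrix2D(t2d)
  h <- (poolFactor - 1) / 2
  bp <- (as.vector(M %*% (h - movingCenter)) + movingCenter +
           t2d@translation - h) / poolFactor
  Mi <- solve(M)
  A <- Mi
  b <- -as.vector(Mi %*% bp)
  res <- .sampleAffine2D(as.numeric(movingImg), dim(movingImg), A, b,
                         dim(fixedImg), 0L, 0)
  inside <- res$inside
  ov <- mean(inside)
  if (ov < minOverlapFraction)
    return(sprintf("insufficient overlap: fraction %.4f below minimum %.4f",
                   ov, minOverlapFraction))
  f <- as.numeric(fixedImg)[inside]
  m <- res$values[inside]
  if (stats::var(f) == 0 || stats::var(m) == 0)
    return("degenerate correlation: a masked signal is constant")
  stats::cor(f, m)
}

#' Register a TEM image to a resolution-matched template
#'
#' Maximizes the 2D Pearson correlation between the template (fixed) and
#' the similarity-transformed TEM image (moving) over rotation and
#' translation, plus an isotropic scale within `scaleBounds` when
#' `allowScale` is TRUE (TEM images occasionally need a slight isotropic
#' rescale to match the LM image exactly; distortion beyond that is
#' negligible, so no elastic model is offered). Uses the same
#' multi-resolution coordinate-search machinery as [affineRegister()],
#' specialized to 2D, and is deterministic.
#'
#' @param template a [SliceTemplate-class] already resampled to the TEM
#'   pixel size (see [resampleTemplate()]).
#' @param tem numeric matrix, the TEM image (8-bit gray).
#' @param temPixelSize the TEM pixel size in micrometres (scalar or
#'   (row, col) pair); must match the template's within 0.5%, otherwise
#'   an error asks the caller to resample first.
#' @param init initial [SimilarityTransform2D-class].
#' @param allowScale optimize the isotropic scale.
#' @param scaleBounds admissible scale interval.
#' @param pyramidLevels,maxIterations,minOverlapFraction,seed as in
#'   [RegistrationConfig()].
#' @return a [RegistrationResult-class] whose transform maps TEM pixel
#'   coordinates to template pixel coordinates (pivot: TEM image center).
#' @export
register2D <- function(template, tem, temPixelSize,
                       init = SimilarityTransform2D(), allowScale = FALSE,
                       scaleBounds = c(0.9, 1.1), pyramidLevels = 4L,
                       maxIterations = 100L, minOverlapFraction = 0.25,
                       seed = 1L) {
  temPixelSize <- rep(as.numeric(temPixelSize), length.out = 2L)
  if (any(abs(temPixelSize - template@pixelSize) >
            0.005 * template@pixelSize))
    stop(sprintf(
      "TEM pixel size (%s um) does not match template pixel size (%s um); resample the template first",
      paste(signif(temPixelSize, 6), collapse = ", "),
      paste(signif(template@pixelSize, 6), collapse = ", ")))
  fixed0 <- template@pixels
  moving0 <- tem
  ctr <- (dim(tem) - 1) / 2

  initCheck <- correlation2D(fixed0, moving0, init, ctr, 1,
                             minOverlapFraction)
  if (is.character(initCheck)) stop(initCheck)

  # pyramid: pool both images while they stay >= 16 px per axis
  fixedLevels <- list(fixed0)
  movingLevels <- list(moving0)
  poolFactors <- 1
  while (length(fixedLevels) < pyramidLevels &&
         all(dim(fixedLevels[[length(fixedLevels)]]) >= 32L) &&
         all(dim(movingLevels[[length(movingLevels)]]) >= 32L)) {
    fixedLevels[[length(fixedLevels) + 1L]] <-
      meanPool2D(fixedLevels[[length(fixedLevels)]])
    movingLevels[[length(movingLevels) + 1L]] <-
      meanPool2D(movingLevels[[length(movingLevels)]])
    poolFactors <- c(poolFactors, poolFactors[length(poolFactors)] * 2)
  }
  nLevels <- length(fixedLevels)

  np <- if (allowScale) 4L else 3L
  p <- c(init@translation, init@angle, if (allowScale) init@scale)
  p0 <- p
  toT <- function(q) SimilarityTransform2D(
    angle = q[3], scale = if (allowScale) q[4] else init@scale,
    translation = q[1:2])

  seedState <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  sweepOrder <- sample.int(np)
  if (!is.null(seedState)) assign(".Random.seed", seedState,
                                  envir = globalenv())

  tol <- c(0.01, 0.01, pi / 180 * 0.01, 1e-4)[c(1, 2, 3, 4)[seq_len(np)]]
  trace <- list()
  converged <- TRUE
  initMetricFine <- initCheck
  for (lvl in nLevels:1) {
    f <- poolFactors[lvl]
    evalAt <- function(q) {
      if (allowScale && (q[4] < scaleBounds[1] || q[4] > scaleBounds[2]))
        return(-Inf)
      r <- correlation2D(fixedLevels[[lvl]], movingLevels[[lvl]], toT(q),
                         ctr, f, minOverlapFraction)
      if (is.character(r)) -Inf else r
    }
    mCur <- evalAt(p)
    mInit <- if (identical(p, p0)) mCur else evalAt(p0)
    if (mInit > mCur) { p <- p0; mCur <- mInit }
    levelIdx <- nLevels - lvl
    steps <- c(2 * f, 2 * f, 2 * pi / 180 / 2^levelIdx,
               if (allowScale) 0.02 / 2^levelIdx)
    acceptedHere <- 0L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      improved <- FALSE
      for (k in sweepOrder) {
        for (s in c(1, -1)) {
          cand <- p
          cand[k] <- cand[k] + s * steps[k]
          mc <- evalAt(cand)
          if (mc > mCur + 1e-7) {
            p <- cand; mCur <- mc; improved <- TRUE
            acceptedHere <- acceptedHere + 1L
            trace[[length(trace) + 1L]] <-
              data.frame(level = lvl, iteration = iter, metric = mc)
            break
          }
        }
      }
      if (!improved) {
        steps <- steps / 2
        if (all(steps < tol)) break
      }
      if (iter >= maxIterations) break
    }
    if (lvl == 1L && acceptedHere == 0L && mCur < initMetricFine - 1e-12)
      converged <- FALSE
  }
  final <- toT(p)
  fm <- correlation2D(fixed0, moving0, final, ctr, 1, minOverlapFraction)
  if (is.character(fm)) stop(fm)
  trace[[length(trace) + 1L]] <-
    data.frame(level = 1L, iteration = NA_integer_, metric = fm)
  new("RegistrationResult", transform = final, finalMetric = fm,
      trace = do.call(rbind, trace), converged = converged)
}

#' Linear levels remap of an 8-bit image
#'
#' Rescales the 8-bit histogram linearly so that input 0 maps to `floor`
#' and input 255 to `ceiling` (default 10..255):
#' `out = round(floor + in * (ceiling - floor) / 255)` with round-half-up.
#' Reserving gray values below the floor for background lets the display
#' colormap ([temAlphaColormap()]) make the background fully transparent
#' while every true image area stays visible.
#'
#' @param image numeric matrix of gray values in 0..255.
#' @param floor,ceiling target range, `0 <= floor < ceiling <= 255`.
#' @return the remapped matrix; monotone in the input.
#' @export
levelsRemap <- function(image, floor = 10L, ceiling = 255L) {
  if (floor >= ceiling) stop("floor must be smaller than ceiling")
  if (floor < 0 || ceiling > 255) stop("floor/ceiling must lie in [0, 255]")
  roundHalfUp(floor + image * (ceiling - floor) / 255)
}

#' Composite a remapped TEM image onto a black template-sized canvas
#'
#' Resamples the (levels-remapped) TEM image into the template's pixel
#' frame through the 2D registration transform. Canvas pixels covered by
#' the transformed TEM footprint hold bilinearly interpolated TEM values,
#' clamped up to `floorValue` so that coverage always implies visibility;
#' uncovered pixels are exactly 0. The canvas size equals the template
#' size -- keeping it unchanged is what allows the template's 3D
#' placement to be reused verbatim for the composited image.
#'
#' @param temRemapped the [levelsRemap()]ed TEM image matrix.
#' @param template the [SliceTemplate-class] the TEM was registered to.
#' @param t2d the [SimilarityTransform2D-class] from [register2D()].
#' @param floorValue the levels-remap floor (background/foreground
#'   separator).
#' @param canvasShape output shape; defaults to (and must be at least)
#'   the template shape.
#' @return numeric matrix of shape `canvasShape`.
#' @export
compositeOnBlack <- function(temRemapped, template, t2d, floorValue = 10L,
                             canvasShape = dim(template@pixels)) {
  if (any(canvasShape < dim(template@pixels)))
    stop(sprintf("canvas (%s) smaller than template shape (%s)",
                 paste(canvasShape, collapse = "x"),
                 paste(dim(template@pixels), collapse = "x")))
  if (min(temRemapped) < floorValue)
    stop("TEM image must be levels-remapped before compositing (min >= floor)")
  ctr <- (dim(temRemapped) - 1) / 2
  sa <- similarityAbout(t2d, ctr)
  Mi <- solve(sa$M)
  A <- Mi
  b <- -as.vector(Mi %*% sa$offset)
  res <- .sampleAffine2D(as.numeric(temRemapped), dim(temRemapped), A, b,
                         as.integer(canvasShape), 0L, 0)
  vals <- roundHalfUp(res$values)
  vals[res$inside] <- pmax(vals[res$inside], floorValue)
  vals[!res$inside] <- 0
  matrix(vals, canvasShape[1], canvasShape[2])
}

#' Embed a composited TEM image in the 3D scene
#'
#' Attaches the full analytic 2D-to-3D mapping to the composited image:
#' the canvas shares the (resampled) template's pixel frame, so its
#' pixel-to-world map is the template's own placement chain (crop
#' geometry, source grid, registered stack transform). The TEM raster is
#' never burnt into a 3D volume; its native resolution is preserved. The
#' display colormap is [temAlphaColormap()], under which the exactly-zero
#' background becomes fully transparent.
#'
#' @param composited matrix from [compositeOnBlack()], same shape as the
#'   template.
#' @param t2d the 2D registration transform (kept as provenance).
#' @param template the resampled [SliceTemplate-class].
#' @return a [PlacedSlice-class].
#' @export
placeIn3D <- function(composited, t2d, template) {
  if (!identical(dim(composited), dim(template@pixels)))
    stop(sprintf("composited shape (%s) must equal template shape (%s)",
                 paste(dim(composited), collapse = "x"),
                 paste(dim(template@pixels), collapse = "x")))
  pm <- templatePixelMap(template)
  new("PlacedSlice", pixels = composited, pixelLinear = pm$linear,
      pixelOrigin = pm$origin, colormap = temAlphaColormap(),
      provenance = list(
        template_slice = template@sliceIndex,
        template_crop = template@cropOffset,
        t2d = list(angle = t2d@angle, scale = t2d@scale,
                   translation = t2d@translation)))
}

#' World coordinates of placed-slice pixels
#'
#' @param placed a [PlacedSlice-class].
#' @param pixels numeric(2) or n x 2 matrix of canvas pixel coordinates.
#' @return world coordinates in micrometres.
#' @export
placedPixelToWorld <- function(placed, pixels) {
  vec <- !is.matrix(pixels)
  if (vec) pixels <- matrix(pixels, 1L)
  w <- sweep(pixels %*% t(placed@pixelLinear), 2L, placed@pixelOrigin, "+")
  if (vec) as.vector(w) else w
}

setMethod("show", "SliceTemplate", function(object) {
  cat(sprintf(
    "SliceTemplate: %s px at %s um/px, slice %d, crop offset (%g, %g)\n",
    paste(dim(object@pixels), collapse = " x "),
    paste(signif(object@pixelSize, 6), collapse = " x "),
    object@sliceIndex, object@cropOffset[1], object@cropOffset[2]))
})

setMethod("show", "PlacedSlice", function(object) {
  cat(sprintf(
    "PlacedSlice: %s px, origin (%s) um, %d background pixel(s)\n",
    paste(dim(object@pixels), collapse = " x "),
    paste(signif(object@pixelOrigin, 5), collapse = ", "),
    sum(object@pixels == 0)))
})
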