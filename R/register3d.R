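#' @include AllClasses.R AllGenerics.R grid.R transforms.R resample.R metric.R
NULL

#' Configuration for affine volume registration
#'
#' @param mode transform freedom: `"rigid"` (rotation + translation),
#'   `"rigid_iso_scale"` (one extra scale) or `"rigid_aniso_scale"`
#'   (per-axis scales, e.g. to correct a systematic section-thickness
#'   error via the z scale).
#' @param pyramidLevels maximum coarse-to-fine levels (the pyramid also
#'   stops before any axis would drop below 16 voxels).
#' @param downsampleFactor pooling factor between levels (2).
#' @param maxIterations parameter sweeps per pyramid level.
#' @param paramTol convergence tolerances for the (translation um,
#'   rotation rad, scale) search steps.
#' @param metricTol minimum metric improvement counted as progress.
#' @param minOverlapFraction required overlap between the volumes.
#' @param seed integer ordering the coordinate sweeps; results are
#'   otherwise deterministic since all overlapping voxels are used (no
#'   stochastic subsampling).
#' @return a [RegistrationConfig-class].
#' @export
RegistrationConfig <- function(mode = "rigid", pyramidLevels = 3L,
                               downsampleFactor = 2L, maxIterations = 100L,
                               paramTol = c(0.01, pi / 180 * 0.01, 1e-4),
                               metricTol = 1e-7, minOverlapFraction = 0.25,
                               seed = 1L) {
  new("RegistrationConfig", mode = mode,
      pyramidLevels = as.integer(pyramidLevels),
      downsampleFactor = as.integer(downsampleFactor),
      metric = "correlation", maxIterations = as.integer(maxIterations),
      paramTol = paramTol, metricTol = metricTol,
      minOverlapFraction = minOverlapFraction, seed = as.integer(seed))
}

## parameter vector layout per mode: (tz, ty, tx, rz, ry, rx [, scales])
paramCount <- function(mode) {
  switch(mode, rigid = 6L, rigid_iso_scale = 7L, rigid_aniso_scale = 9L)
}

paramsToTransform <- function(p, mode, center) {
  scales <- switch(mode, rigid = c(1, 1, 1),
                   rigid_iso_scale = rep(p[7], 3L),
                   rigid_aniso_scale = p[7:9])
  eulerTransform3D(angles = p[4:6], translation = p[1:3], scales = scales,
                   center = center, mode = mode)
}

transformToParams <- function(transform, mode, center) {
  d <- decomposeAffine3D(transform, center)
  p <- c(d$translation, d$angles)
  if (mode == "rigid_iso_scale") p <- c(p, mean(d$scales))
  if (mode == "rigid_aniso_scale") p <- c(p, d$scales)
  p
}

## tolerance class of each parameter: 1 translation, 2 rotation, 3 scale
paramTolIndex <- function(mode) {
  c(rep(1L, 3), rep(2L, 3), rep(3L, paramCount(mode) - 6L))
}

#' Automatic affine co-registration of two volumes
#'
#' Finds the transform (moving world to fixed world) maximizing the
#' Pearson [correlationMetric()] by a multi-resolution, derivative-free
#' coordinate search. The moving volume should be preprocessed to match
#' the fixed volume's contrast polarity first (see
#' [preprocessForRegistration()]); the degree of similarity between the
#' datasets has a major effect on the result. The initial transform is
#' always caller-supplied, mirroring a manual coarse alignment;
#' [centroidAxesInit()] can compute a data-driven guess but is never
#' applied silently.
#'
#' Per pyramid level the search sweeps the transform parameters (3
#' rotations + 3 translations, plus 1 or 3 scales depending on mode) in a
#' seed-determined order, stepping each by +/- the current step size and
#' accepting improvements; after a sweep with no acceptance all steps are
#' halved, until they drop below `paramTol`. Steps start at 2 voxels,
#' 2 degrees and 2% scale at the coarsest level. All overlapping voxels
#' enter the metric at every level, so the procedure is deterministic
#' given the config.
#'
#' @param fixed the reference [VolumeImage-class] (e.g. microCT, free
#'   from geometric distortion).
#' @param moving the preprocessed moving [VolumeImage-class] (e.g. the
#'   inverted, smoothed LM stack).
#' @param init initial [AffineTransform3D-class]; must give at least
#'   `minOverlapFraction` overlap.
#' @param config a [RegistrationConfig-class].
#' @return a [RegistrationResult-class]; `converged` is FALSE when the
#'   finest level accepted no step and ended below the initial metric.
#' @export
affineRegister <- function(fixed, moving, init = identityTransform3D(),
                           config = RegistrationConfig()) {
  mode <- config@mode
  center <- gridCenter(moving@grid)
  # fail loudly if the initial alignment is unusable (also catches
  # degenerate constant regions)
  initCheck <- correlationCore(fixed@voxels, fixed@grid, moving@voxels,
                               moving@grid, init, config@minOverlapFraction)
  if (is.character(initCheck)) stop(initCheck)
  initMetricFine <- initCheck$metric

  # build the coarse-to-fine pyramid (element 1 = finest = original)
  fixedLevels <- list(fixed)
  movingLevels <- list(moving)
  while (length(fixedLevels) < config@pyramidLevels) {
    pf <- poolLevel(fixedLevels[[length(fixedLevels)]])
    pm <- poolLevel(movingLevels[[length(movingLevels)]])
    if (is.null(pf) && is.null(pm)) break
    fixedLevels[[length(fixedLevels) + 1L]] <-
      if (is.null(pf)) fixedLevels[[length(fixedLevels)]] else pf
    movingLevels[[length(movingLevels) + 1L]] <-
      if (is.null(pm)) movingLevels[[length(movingLevels)]] else pm
  }
  nLevels <- length(fixedLevels)

  np <- paramCount(mode)
  tolIdx <- paramTolIndex(mode)
  tol <- config@paramTol[tolIdx]
  p0 <- transformToParams(init, mode, center)
  p <- p0

  # the seed orders the coordinate sweeps; keep the caller's RNG intact
  seedState <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(config@seed)
  sweepOrder <- sample.int(np)
  if (!is.null(seedState)) assign(".Random.seed", seedState,
                                  envir = globalenv())

  trace <- list()
  converged <- TRUE
  for (lvl in nLevels:1) {
    fl <- fixedLevels[[lvl]]
    ml <- movingLevels[[lvl]]
    evalAt <- function(q) {
      r <- correlationCore(fl@voxels, fl@grid, ml@voxels, ml@grid,
                           paramsToTransform(q, mode, center),
                           config@minOverlapFraction)
      if (is.character(r)) -Inf else r$metric
    }
    # start each level from the better of the propagated and the initial
    # parameters, so the finest metric can never end below the init metric
    mCur <- evalAt(p)
    mInit <- if (identical(p, p0)) mCur else evalAt(p0)
    if (mInit > mCur) { p <- p0; mCur <- mInit }
    levelIdx <- nLevels - lvl   # 0 at the coarsest level
    steps <- c(2 * fl@grid@spacing, rep(2 * pi / 180 / 2^levelIdx, 3),
               rep(0.02 / 2^levelIdx, np - 6L))
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
          if (mc > mCur + config@metricTol) {
            p <- cand
            mCur <- mc
            improved <- TRUE
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
      if (iter >= config@maxIterations) break
    }
    if (lvl == 1L && acceptedHere == 0L && mCur < initMetricFine - 1e-12)
      converged <- FALSE
  }

  final <- paramsToTransform(p, mode, center)
  finalMetric <- correlationMetric(fixed, moving, final,
                                   config@minOverlapFraction)
  trace[[length(trace) + 1L]] <-
    data.frame(level = 1L, iteration = NA_integer_, metric = finalMetric)
  new("RegistrationResult", transform = final, finalMetric = finalMetric,
      trace = do.call(rbind, trace), converged = converged)
}

#' Propagate a registration transform to companion stacks
#'
#' Applies the transform estimated on the preprocessed moving stack to
#' its companions on the same grid -- the original (non-inverted,
#' unfiltered) LM stack and the segmentation label volume -- so all of
#' them become co-registered with the reference. Without `resampleTo`
#' each companion is paired with exactly the same transform object;
#' with a target grid the companions are resampled (linear interpolation
#' for gray volumes, nearest for labels).
#'
#' @param companions list of [VolumeImage-class] / [LabelVolume-class]
#'   objects sharing the moving stack's grid.
#' @param transform the estimated [AffineTransform3D-class].
#' @param movingGrid the moving stack's [ImageGrid-class] (for the grid
#'   compatibility check).
#' @param resampleTo optional target [ImageGrid-class].
#' @return without `resampleTo`: a list of `list(data, transform)` pairs
#'   (the identical transform object in each); with it: a list of
#'   resampled objects.
#' @export
propagateTransform <- function(companions, transform, movingGrid,
                               resampleTo = NULL) {
  for (comp in companions) {
    g <- imageGrid(comp)
    if (!isTRUE(all.equal(g@shape, movingGrid@shape)) ||
        !isTRUE(all.equal(g@spacing, movingGrid@spacing)) ||
        !isTRUE(all.equal(g@origin, movingGrid@origin)))
      stop(sprintf(
        "companion grid (%s @ %s um) does not match moving grid (%s @ %s um)",
        paste(g@shape, collapse = "x"),
        paste(signif(g@spacing, 6), collapse = "x"),
        paste(movingGrid@shape, collapse = "x"),
        paste(signif(movingGrid@spacing, 6), collapse = "x")))
  }
  if (is.null(resampleTo))
    lapply(companions, function(comp) list(data = comp,
                                           transform = transform))
  else
    lapply(companions, function(comp)
      resampleVolume(comp, resampleTo, transform,
                     if (is(comp, "LabelVolume")) "nearest" else "linear"))
}

#' Data-driven initial alignment guess
#'
#' Computes a rigid initial transform aligning the intensity centroid and
#' principal axes of the moving volume to those of the fixed volume. A
#' helper for cases where no manual coarse alignment is available; it is
#' never applied automatically by [affineRegister()], and principal-axis
#' sign ambiguities make it unreliable for near-symmetric specimens.
#'
#' @param fixed,moving [VolumeImage-class] objects.
#' @return a rigid [AffineTransform3D-class] guess.
#' @export
centroidAxesInit <- function(fixed, moving) {
  momentFrame <- function(v) {
    w <- as.numeric(v@voxels)
    w <- w - min(w)
    if (sum(w) == 0) stop("cannot orient a constant volume")
    idx <- cbind(as.numeric(slice.index(v@voxels, 1)) - 1,
                 as.numeric(slice.index(v@voxels, 2)) - 1,
                 as.numeric(slice.index(v@voxels, 3)) - 1)
    pos <- voxelToWorld(v@grid, idx)
    ctr <- colSums(pos * w) / sum(w)
    d <- sweep(pos, 2L, ctr)
    M <- crossprod(d * sqrt(w / sum(w)))
    e <- eigen(M, symmetric = TRUE)
    U <- e$vectors
    # fix signs: dominant component of each axis positive
    for (j in 1:3) if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
    if (det(U) < 0) U[, 3] <- -U[, 3]
    list(center = ctr, axes = U)
  }
  ff <- momentFrame(fixed)
  mf <- momentFrame(moving)
  R <- ff$axes %*% t(mf$axes)
  AffineTransform3D(R, ff$center - as.vector(R %*% mf$center), "rigid")
}
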