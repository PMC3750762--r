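#' @include AllClasses.R AllGenerics.R grid.R transforms.R
NULL

## Affine map from target-grid voxel indices to moving-grid continuous
## indices, going through world space and the (inverted) transform:
## j = A i + b. This is what the C++ samplers consume.
indexMap <- function(targetGrid, movingGrid, transform) {
  Ti <- invert(transform)
  A <- diag(1 / movingGrid@spacing) %*% Ti@linear %*% diag(targetGrid@spacing)
  b <- (as.vector(Ti@linear %*% targetGrid@origin) + Ti@translation -
          movingGrid@origin) / movingGrid@spacing
  list(A = A, b = b)
}

#' Resample a volume onto a target grid through a transform
#'
#' Each target voxel takes the value of the moving volume at the world
#' position `invert(transform)(voxel center)`; positions outside the
#' moving volume's physical extent take fill value 0. Gray volumes may use
#' linear or nearest interpolation; label volumes must use nearest (linear
#' interpolation would invent labels). The occupancy mask (which target
#' voxels landed inside the moving extent) is attached to the result as
#' the `"occupancy"` attribute of its voxel array.
#'
#' @param moving a [VolumeImage-class] or [LabelVolume-class].
#' @param targetGrid the output [ImageGrid-class].
#' @param transform an [AffineTransform3D-class], moving world to fixed
#'   (target) world.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return a resampled object of the same class as `moving`, on
#'   `targetGrid`.
#' @export
resampleVolume <- function(moving, targetGrid, transform,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  isLabels <- is(moving, "LabelVolume")
  if (isLabels && interpolation != "nearest")
    stop("label volumes must be resampled with nearest interpolation")
  src <- if (isLabels) moving@labels else moving@voxels
  map <- indexMap(targetGrid, moving@grid, transform)
  res <- .sampleAffine3D(as.numeric(src), dim(src), map$A, map$b,
                         targetGrid@shape,
                         if (interpolation == "linear") 0L else 1L, 0)
  vals <- array(res$values, targetGrid@shape)
  occ <- array(res$inside, targetGrid@shape)
  if (isLabels) {
    out <- LabelVolume(vals, targetGrid, moving@labelNames)
    attr(out@labels, "occupancy") <- occ
  } else {
    if (interpolation == "linear") vals <- floor(vals + 0.5)
    out <- VolumeImage(vals, targetGrid, moving@modality)
    attr(out@voxels, "occupancy") <- occ
  }
  out
}

## factor-2 mean-pool pyramid level of a volume; axes that would drop
## below 16 voxels are left unpooled, NULL once nothing can be pooled
poolLevel <- function(volume) {
  shp <- volume@grid@shape
  poolable <- shp >= 32L
  if (!any(poolable)) return(NULL)
  vox <- volume@voxels
  # pool all poolable axes with the C++ kernel, then undo unpoolable ones
  # by only pooling along poolable axes: emulate per-axis pooling in R
  for (axis in which(poolable)) {
    d <- dim(vox)
    n2 <- d[axis] %/% 2L
    idx1 <- seq_len(n2) * 2L - 1L
    idx2 <- seq_len(n2) * 2L
    vox <- switch(axis,
      (vox[idx1, , , drop = FALSE] + vox[idx2, , , drop = FALSE]) / 2,
      (vox[, idx1, , drop = FALSE] + vox[, idx2, , drop = FALSE]) / 2,
      (vox[, , idx1, drop = FALSE] + vox[, , idx2, drop = FALSE]) / 2)
  }
  spacing <- ifelse(poolable, volume@grid@spacing * 2, volume@grid@spacing)
  origin <- ifelse(poolable, volume@grid@origin + volume@grid@spacing / 2,
                   volume@grid@origin)
  out <- volume
  out@voxels <- vox
  out@grid <- ImageGrid(dim(vox), spacing, origin)
  out
}
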