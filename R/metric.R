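#' @include AllClasses.R AllGenerics.R grid.R transforms.R resample.R
NULL

## metric core shared by correlationMetric() and the optimizer: returns
## list(metric, overlapFraction, n) or a character error tag when the
## overlap is insufficient / a masked signal is constant
correlationCore <- function(fixedVox, fixedGrid, movingVox, movingGrid,
                            transform, minOverlapFraction) {
  map <- indexMap(fixedGrid, movingGrid, transform)
  res <- .sampleAffine3D(as.numeric(movingVox), dim(movingVox),
                         map$A, map$b, fixedGrid@shape, 0L, 0)
  inside <- res$inside
  ov <- mean(inside)
  if (ov < minOverlapFraction)
    return(sprintf("insufficient overlap: fraction %.4f below minimum %.4f",
                   ov, minOverlapFraction))
  f <- as.numeric(fixedVox)[inside]
  m <- res$values[inside]
  if (stats::var(f) == 0 || stats::var(m) == 0)
    return("degenerate correlation: a masked signal is constant")
  list(metric = stats::cor(f, m), overlapFraction = ov, n = length(f))
}

#' Correlation metric between a fixed and a transformed moving volume
#'
#' Pearson correlation coefficient between the fixed volume's voxel
#' values and the moving volume's values, linearly interpolated at the
#' positions the transform maps each fixed voxel center to. The
#' correlation is computed over exactly the fixed voxels whose mapped
#' position falls inside the moving volume's physical extent. This is the
#' objective maximized by [affineRegister()].
#'
#' @param fixed,moving [VolumeImage-class] objects.
#' @param transform an [AffineTransform3D-class] (moving world to fixed
#'   world).
#' @param minOverlapFraction error out if fewer than this fraction of
#'   fixed voxels map inside the moving extent.
#' @param details if TRUE return a list with `metric`, `overlapFraction`
#'   and `n` instead of the bare coefficient.
#' @return correlation in \[-1, 1\], or a detail list.
#' @export
correlationMetric <- function(fixed, moving, transform,
                              minOverlapFraction = 0.25, details = FALSE) {
  r <- correlationCore(fixed@voxels, fixed@grid, moving@voxels,
                       moving@grid, transform, minOverlapFraction)
  if (is.character(r)) stop(r)
  if (details) r else r$metric
}
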