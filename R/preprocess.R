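#' @include AllClasses.R AllGenerics.R grid.R
NULL

#' Gaussian filter specification
#'
#' The smoothing used to make the LM stack resemble the microCT stack
#' before metric-driven registration. The default 3x3x3 support matches a
#' radius-1 kernel per axis; sigma defaults to 0.8 voxels, a common choice
#' for a radius-1 Gaussian, and is a tunable knob since the GUI pipeline
#' this mirrors does not publish its parameterization.
#'
#' @param kernelSize odd integer support per axis, recycled to length 3.
#' @param sigma positive standard deviation per axis (voxels), recycled.
#' @return a [GaussianSpec-class].
#' @export
GaussianSpec <- function(kernelSize = 3L, sigma = 0.8) {
  new("GaussianSpec",
      kernelSize = rep(as.integer(kernelSize), length.out = 3L),
      sigma = rep(as.numeric(sigma), length.out = 3L))
}

## normalized sampled-Gaussian weights for one axis
gaussianKernel1D <- function(size, sigma) {
  r <- (size - 1L) %/% 2L
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Invert the gray values of a volume
#'
#' Every voxel v becomes 255 - v, turning the LM stack's dark-on-bright
#' contrast into the microCT's bright-on-dark polarity so that a
#' correlation metric sees the two modalities as similar. Applying the
#' operation twice returns the original volume.
#'
#' @param volume an 8-bit [VolumeImage-class].
#' @return the inverted [VolumeImage-class] on the same grid.
#' @examples
#' v <- VolumeImage(array(c(0, 100, 255, 7), c(1, 2, 2)))
#' voxelData(invertIntensities(v))
#' @export
invertIntensities <- function(volume) {
  out <- volume
  out@voxels <- 255 - volume@voxels
  out
}

## separable convolution along one axis of a (z, y, x) array with
## edge replication, implemented as a weighted sum of clamped-index shifts
convolveAxis <- function(arr, w, axis) {
  n <- dim(arr)[axis]
  r <- (length(w) - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (k in seq_along(w)) {
    off <- k - 1L - r
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + w[k] * shifted
  }
  out
}

#' Gaussian smoothing of a volume
#'
#' Separable 3D convolution with the normalized sampled-Gaussian kernel
#' of `spec`. Borders are handled by edge replication (zero padding would
#' darken the specimen borders and bias the registration metric toward
#' background). The result is re-quantized to 8 bits by round-half-up
#' unless `quantize = FALSE`, mirroring a pipeline of 8-bit processing
#' modules.
#'
#' @param volume a [VolumeImage-class].
#' @param spec a [GaussianSpec-class]; default 3x3x3 support, sigma 0.8.
#' @param quantize logical; set FALSE to keep float values (testing).
#' @return the smoothed [VolumeImage-class] on the same grid.
#' @export
gaussianSmooth <- function(volume, spec = GaussianSpec(), quantize = TRUE) {
  shp <- volume@grid@shape
  if (any(spec@kernelSize > shp))
    stop(sprintf("kernel (%s) larger than volume extent (%s)",
                 paste(spec@kernelSize, collapse = "/"),
                 paste(shp, collapse = "/")))
  arr <- volume@voxels
  for (axis in 1:3) {
    if (spec@kernelSize[axis] > 1L)
      arr <- convolveAxis(arr, gaussianKernel1D(spec@kernelSize[axis],
                                                spec@sigma[axis]), axis)
  }
  out <- volume
  out@voxels <- if (quantize) roundHalfUp(arr) else arr
  out
}

#' Standard preprocessing of an LM stack for co-registration
#'
#' Convenience wrapper chaining [invertIntensities()] and
#' [gaussianSmooth()], the two similarity-enhancing steps applied to the
#' LM serial-section stack before correlation-driven registration against
#' the microCT reference.
#'
#' @param volume the LM [VolumeImage-class].
#' @param spec a [GaussianSpec-class].
#' @return the preprocessed [VolumeImage-class].
#' @export
preprocessForRegistration <- function(volume, spec = GaussianSpec()) {
  gaussianSmooth(invertIntensities(volume), spec)
}
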