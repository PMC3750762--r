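#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an image grid
#'
#' @param shape integer(3) voxel counts (nz, ny, nx).
#' @param spacing numeric(3) voxel size (sz, sy, sx) in micrometres.
#' @param origin numeric(3) world coordinate of the center of voxel
#'   (0, 0, 0), micrometres; defaults to (0, 0, 0).
#' @return an [ImageGrid-class] object.
#' @examples
#' # the LM serial-section lattice: 585 sections of 1200 x 1600 pixels
#' g <- ImageGrid(c(585L, 1200L, 1600L), c(1.5, 0.413, 0.413))
#' voxelToWorld(g, c(1, 1, 1))
#' @export
ImageGrid <- function(shape, spacing, origin = c(0, 0, 0)) {
  new("ImageGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct an intensity volume
#'
#' @param voxels numeric array with dim (nz, ny, nx), values in 0..255.
#' @param grid the [ImageGrid-class] the voxels live on; defaults to unit
#'   spacing (but see [readStack()], which never defaults spacing).
#' @param modality `"microct"`, `"lm"` or `"other"`.
#' @return a [VolumeImage-class].
#' @export
VolumeImage <- function(voxels, grid = NULL, modality = "other") {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "double"
  if (is.null(grid)) grid <- ImageGrid(dim(voxels), c(1, 1, 1))
  new("VolumeImage", voxels = voxels, grid = grid, modality = modality)
}

#' Construct a label volume
#'
#' @param labels integer array with dim (nz, ny, nx), 0 = background.
#' @param grid the [ImageGrid-class].
#' @param labelNames named character vector mapping label ids (as names)
#'   to organ-system names.
#' @return a [LabelVolume-class].
#' @export
LabelVolume <- function(labels, grid, labelNames = character()) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, grid = grid,
      labelNames = labelNames)
}

#' Map voxel indices to world coordinates
#'
#' Voxel index (0-based, possibly fractional or out of range) to physical
#' world coordinate in micrometres: `world = origin + index * spacing`,
#' componentwise in (z, y, x) order. The mapping is affine; a voxel's
#' world coordinate is the coordinate of its center.
#'
#' @param grid an [ImageGrid-class].
#' @param index numeric(3) or an n x 3 matrix of indices.
#' @return world coordinates with the same shape as `index`.
#' @export
voxelToWorld <- function(grid, index) {
  if (is.matrix(index))
    sweep(sweep(index, 2L, grid@spacing, "*"), 2L, grid@origin, "+")
  else grid@origin + index * grid@spacing
}

#' Map world coordinates to voxel indices
#'
#' Exact inverse of [voxelToWorld()].
#'
#' @param grid an [ImageGrid-class].
#' @param world numeric(3) or an n x 3 matrix of world coordinates (um).
#' @return fractional 0-based voxel indices.
#' @export
worldToVoxel <- function(grid, world) {
  if (is.matrix(world))
    sweep(sweep(world, 2L, grid@origin, "-"), 2L, grid@spacing, "/")
  else (world - grid@origin) / grid@spacing
}

## world coordinate of the lattice's physical center (rotation pivot)
gridCenter <- function(grid) {
  grid@origin + (grid@shape - 1) / 2 * grid@spacing
}

#' @name accessors
#' @title Accessors for tricoreg objects
#' @param x an object.
#' @description Slot accessors: grids, voxel/label data, transform parts,
#'   registration results, opacity tables.
NULL

#' @rdname accessors
#' @export
setMethod("imageGrid", "VolumeImage", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("imageGrid", "LabelVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("voxelData", "VolumeImage", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("modality", "VolumeImage", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("labelData", "LabelVolume", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("labelNames", "LabelVolume", function(x) x@labelNames)
#' @rdname accessors
#' @export
setMethod("gridShape", "ImageGrid", function(x) x@shape)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "ImageGrid", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "ImageGrid", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("registeredTransform", "RegistrationResult", function(x) x@transform)
#' @rdname accessors
#' @export
setMethod("finalMetric", "RegistrationResult", function(x) x@finalMetric)
#' @rdname accessors
#' @export
setMethod("metricTrace", "RegistrationResult", function(x) x@trace)
#' @rdname accessors
#' @export
setMethod("hasConverged", "RegistrationResult", function(x) x@converged)
#' @rdname accessors
#' @export
setMethod("opacityTable", "AlphaColormap", function(x) x@opacity)

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels, spacing %s um, origin %s um\n",
              paste(object@shape, collapse = " x "),
              paste(signif(object@spacing, 6), collapse = " x "),
              paste(signif(object@origin, 6), collapse = ", ")))
})

setMethod("show", "VolumeImage", function(object) {
  cat(sprintf("VolumeImage [%s]: %s voxels, spacing %s um, gray range [%d, %d]\n",
              object@modality,
              paste(object@grid@shape, collapse = " x "),
              paste(signif(object@grid@spacing, 6), collapse = " x "),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "LabelVolume", function(object) {
  present <- setdiff(sort(unique(as.vector(object@labels))), 0L)
  cat(sprintf("LabelVolume: %s voxels, %d label(s): %s\n",
              paste(object@grid@shape, collapse = " x "),
              length(present),
              paste(object@labelNames[as.character(present)],
                    collapse = ", ")))
})
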