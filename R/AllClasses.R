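#' @importFrom methods new validObject setClass setValidity is slot
#' @importFrom Rcpp evalCpp
#' @useDynLib tricoreg, .registration = TRUE
NULL

## Index and world coordinates are ordered (z, y, x) = (slice, row, column)
## throughout; voxel indices are 0-based and a voxel's world coordinate is
## the coordinate of its CENTER. Multi-page TIFF storage is slice-major,
## which makes (z, y, x) the natural axis order.

#' Regular image lattice in physical coordinates
#'
#' An `ImageGrid` ties a voxel lattice to physical space: `shape` counts
#' voxels per axis, `spacing` is the voxel size in micrometres, and `origin`
#' is the world coordinate (in micrometres) of the center of voxel
#' \eqn{(0, 0, 0)}. Axes are ordered (z, y, x) = (slice, row, column).
#'
#' @slot shape integer(3), voxel counts per axis, all >= 1.
#' @slot spacing numeric(3), voxel size in micrometres, all > 0.
#' @slot origin numeric(3), world position of the first voxel center (um).
#' @export
setClass("ImageGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  prototype(shape = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("ImageGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three voxel counts, all >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values (um)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite world coordinates (um)")
  if (length(msg)) msg else TRUE
})

#' 8-bit intensity volume on a physical grid
#'
#' Carries a microCT or LM stack: an array of gray values in \[0, 255\]
#' with dim = `shape(grid)` (z, y, x order) plus its [ImageGrid] and a
#' modality tag (`"microct"`, `"lm"` or `"other"`).
#'
#' @slot voxels numeric array, dim (nz, ny, nx), integral values in 0..255.
#' @slot grid an [ImageGrid].
#' @slot modality character scalar tag.
#' @export
setClass("VolumeImage",
  representation(voxels = "array", grid = "ImageGrid", modality = "character"))

setValidity("VolumeImage", function(object) {
  msg <- character()
  if (!identical(dim(object@voxels), as.integer(object@grid@shape)))
    msg <- c(msg, "voxel array dim must equal grid shape (z, y, x)")
  rng <- range(object@voxels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    msg <- c(msg, "voxel values must lie in [0, 255]")
  if (!(length(object@modality) == 1L &&
        object@modality %in% c("microct", "lm", "other")))
    msg <- c(msg, "modality must be one of 'microct', 'lm', 'other'")
  if (length(msg)) msg else TRUE
})

#' Segmentation label volume
#'
#' Integer labels on an [ImageGrid]; 0 is background and carries no name,
#' every non-zero label present in the volume must be named (e.g. organ
#' systems segmented from the LM stack).
#'
#' @slot labels integer array, dim (nz, ny, nx), values >= 0.
#' @slot grid an [ImageGrid].
#' @slot labelNames named character; names are label ids as strings.
#' @export
setClass("LabelVolume",
  representation(labels = "array", grid = "ImageGrid", labelNames = "character"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), as.integer(object@grid@shape)))
    msg <- c(msg, "label array dim must equal grid shape (z, y, x)")
  if (any(object@labels < 0))
    msg <- c(msg, "labels must be non-negative integers (0 = background)")
  present <- setdiff(unique(as.vector(object@labels)), 0)
  nm <- names(object@labelNames)
  if ("0" %in% nm)
    msg <- c(msg, "label 0 is background and must not be named")
  missing <- setdiff(as.character(present), nm)
  if (length(missing))
    msg <- c(msg, paste0("unnamed labels present in volume: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Affine map between physical coordinate frames
#'
#' Maps moving-world to fixed-world coordinates (both in micrometres,
#' (z, y, x) order): \eqn{p \mapsto L p + t}. The `mode` records how much
#' freedom the map was allowed: `"rigid"` (rotation + translation),
#' `"rigid_iso_scale"` (plus one isotropic scale) or `"rigid_aniso_scale"`
#' (plus per-axis scales). Mode is metadata enforced on construction.
#'
#' @slot linear numeric 3x3 matrix, invertible.
#' @slot translation numeric(3), micrometres.
#' @slot mode character scalar.
#' @slot convention fixed string `"moving_world_to_fixed_world"`.
#' @export
setClass("AffineTransform3D",
  representation(linear = "matrix", translation = "numeric",
                 mode = "character", convention = "character"),
  prototype(linear = diag(3), translation = c(0, 0, 0), mode = "rigid",
            convention = "moving_world_to_fixed_world"))

setValidity("AffineTransform3D", function(object) {
  msg <- character()
  L <- object@linear
  if (!is.numeric(L) || !identical(dim(L), c(3L, 3L)))
    msg <- c(msg, "linear must be a numeric 3x3 matrix")
  else {
    d <- det(L)
    if (abs(d) <= 1e-12)
      msg <- c(msg, "linear part is singular (|det| <= 1e-12)")
    if (object@mode == "rigid" && abs(d) > 1e-12) {
      if (max(abs(crossprod(L) - diag(3))) > 1e-9 || abs(d - 1) > 1e-9)
        msg <- c(msg, "rigid mode requires an orthogonal linear part with det = +1")
    }
    if (object@mode == "rigid_iso_scale" && d > 0) {
      s <- d^(1 / 3)
      R <- L / s
      if (max(abs(crossprod(R) - diag(3))) > 1e-9)
        msg <- c(msg, "rigid_iso_scale mode requires linear = s * R with R orthogonal")
    }
  }
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be three finite values (um)")
  if (!(object@mode %in% c("rigid", "rigid_iso_scale", "rigid_aniso_scale")))
    msg <- c(msg, "mode must be rigid, rigid_iso_scale or rigid_aniso_scale")
  if (!identical(object@convention, "moving_world_to_fixed_world"))
    msg <- c(msg, "convention must be 'moving_world_to_fixed_world'")
  if (length(msg)) msg else TRUE
})

#' In-plane similarity transform for TEM-to-template registration
#'
#' Rotation by `angle` (radians) and isotropic `scale` about the moving
#' image's center, followed by `translation` in template pixels; maps TEM
#' (moving) pixel coordinates to template (fixed) pixel coordinates,
#' (row, col) order.
#'
#' @slot angle numeric scalar, radians.
#' @slot scale positive numeric scalar.
#' @slot translation numeric(2), template pixels (row, col).
#' @export
setClass("SimilarityTransform2D",
  representation(angle = "numeric", scale = "numeric", translation = "numeric"),
  prototype(angle = 0, scale = 1, translation = c(0, 0)))

setValidity("SimilarityTransform2D", function(object) {
  msg <- character()
  if (length(object@angle) != 1L || !is.finite(object@angle))
    msg <- c(msg, "angle must be a finite scalar (radians)")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    msg <- c(msg, "scale must be a positive scalar")
  if (length(object@translation) != 2L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be two finite values (pixels)")
  if (length(msg)) msg else TRUE
})

#' Outcome of a metric-driven registration
#'
#' @slot transform the estimated [AffineTransform3D] or
#'   [SimilarityTransform2D].
#' @slot finalMetric Pearson correlation at the optimum, in \[-1, 1\].
#' @slot trace data.frame with columns `level`, `iteration`, `metric`
#'   recording every accepted step, coarse to fine.
#' @slot converged logical flag.
#' @export
setClass("RegistrationResult",
  representation(transform = "ANY", finalMetric = "numeric",
                 trace = "data.frame", converged = "logical"))

setValidity("RegistrationResult", function(object) {
  msg <- character()
  tr <- object@trace
  if (nrow(tr)) {
    if (any(tr$metric < -1 - 1e-9 | tr$metric > 1 + 1e-9))
      msg <- c(msg, "trace metric values must lie in [-1, 1]")
    if (abs(object@finalMetric - tr$metric[nrow(tr)]) > 1e-12)
      msg <- c(msg, "finalMetric must equal the last trace entry")
  }
  if (length(msg)) msg else TRUE
})

#' Opacity lookup table for slice display
#'
#' 256 opacity entries in \[0, 255\], indexed by 8-bit gray value (entry 1
#' corresponds to gray 0).
#'
#' @slot opacity integer(256) in \[0, 255\].
#' @export
setClass("AlphaColormap", representation(opacity = "integer"))

setValidity("AlphaColormap", function(object) {
  if (length(object@opacity) != 256L)
    return("opacity table must have exactly 256 entries")
  if (any(object@opacity < 0L | object@opacity > 255L))
    return("opacity entries must lie in [0, 255]")
  TRUE
})

#' Separable Gaussian filter specification
#'
#' @slot kernelSize integer(3), odd support per axis in voxels.
#' @slot sigma numeric(3), standard deviation per axis in voxels.
#' @export
setClass("GaussianSpec",
  representation(kernelSize = "integer", sigma = "numeric"),
  prototype(kernelSize = c(3L, 3L, 3L), sigma = c(0.8, 0.8, 0.8)))

setValidity("GaussianSpec", function(object) {
  msg <- character()
  if (length(object@kernelSize) != 3L || any(object@kernelSize < 1L) ||
      any(object@kernelSize %% 2L == 0L))
    msg <- c(msg, "kernelSize must be three odd integers >= 1")
  if (length(object@sigma) != 3L || any(object@sigma <= 0))
    msg <- c(msg, "sigma must be three positive values (voxels)")
  if (length(msg)) msg else TRUE
})

#' Settings for the affine volume registration
#'
#' @slot mode transform freedom: `"rigid"`, `"rigid_iso_scale"` or
#'   `"rigid_aniso_scale"`.
#' @slot pyramidLevels integer >= 1; coarse-to-fine resolution levels.
#' @slot downsampleFactor integer >= 2; pooling factor between levels.
#' @slot metric fixed tag `"correlation"`.
#' @slot maxIterations integer; parameter sweeps per level.
#' @slot paramTol numeric(3): convergence tolerance for translation (um),
#'   rotation (radians) and scale (unitless) steps.
#' @slot metricTol numeric; improvement below this never counts as progress.
#' @slot minOverlapFraction numeric in (0, 1].
#' @slot seed integer; orders the coordinate sweeps.
#' @export
setClass("RegistrationConfig",
  representation(mode = "character", pyramidLevels = "integer",
                 downsampleFactor = "integer", metric = "character",
                 maxIterations = "integer", paramTol = "numeric",
                 metricTol = "numeric", minOverlapFraction = "numeric",
                 seed = "integer"),
  prototype(mode = "rigid", pyramidLevels = 3L, downsampleFactor = 2L,
            metric = "correlation", maxIterations = 100L,
            paramTol = c(0.01, 0.000175, 1e-4), metricTol = 1e-7,
            minOverlapFraction = 0.25, seed = 1L))

setValidity("RegistrationConfig", function(object) {
  msg <- character()
  if (!(object@mode %in% c("rigid", "rigid_iso_scale", "rigid_aniso_scale")))
    msg <- c(msg, "unknown registration mode")
  if (object@pyramidLevels < 1L) msg <- c(msg, "pyramidLevels must be >= 1")
  if (object@downsampleFactor < 2L)
    msg <- c(msg, "downsampleFactor must be >= 2")
  if (!identical(object@metric, "correlation"))
    msg <- c(msg, "the only supported metric is 'correlation'")
  if (length(object@paramTol) != 3L || any(object@paramTol <= 0))
    msg <- c(msg, "paramTol must be three positive tolerances")
  if (object@metricTol <= 0) msg <- c(msg, "metricTol must be > 0")
  if (object@minOverlapFraction <= 0 || object@minOverlapFraction > 1)
    msg <- c(msg, "minOverlapFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cropped, placement-aware copy of one registered LM slice
#'
#' A 2D crop of a single slice of the registered LM stack that remembers
#' everything needed to map each of its pixels back to 3D world
#' coordinates: the source grid, the slice index, the crop offset and the
#' stack's world transform. Serves as the fixed image for TEM registration.
#'
#' @slot pixels numeric matrix (rows x cols), gray values in 0..255.
#' @slot pixelSize numeric(2), (row, col) pixel size in micrometres.
#' @slot sliceIndex integer, 0-based slice within the source stack.
#' @slot cropOffset numeric(2), (row, col) crop origin in source voxels;
#'   fractional after resampling-induced edge anchoring is not needed, so
#'   stays integral in practice.
#' @slot sourceTransform the registered stack's [AffineTransform3D].
#' @slot sourceGrid the stack's [ImageGrid].
#' @export
setClass("SliceTemplate",
  representation(pixels = "matrix", pixelSize = "numeric",
                 sliceIndex = "integer", cropOffset = "numeric",
                 sourceTransform = "AffineTransform3D",
                 sourceGrid = "ImageGrid"))

setValidity("SliceTemplate", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    msg <- c(msg, "pixelSize must be two positive values (um)")
  if (any(object@cropOffset < 0))
    msg <- c(msg, "cropOffset must be >= (0, 0)")
  if (object@sliceIndex < 0L ||
      object@sliceIndex >= object@sourceGrid@shape[1])
    msg <- c(msg, "sliceIndex outside the source stack")
  if (length(msg)) msg else TRUE
})

#' TEM image embedded in the 3D scene
#'
#' The composited (black-background, levels-remapped) TEM image together
#' with the affine map from its 2D pixel coordinates to 3D world
#' coordinates and the transparency colormap used for display. The mapping
#' is stored analytically; the TEM raster is never burnt into a 3D volume,
#' preserving its native resolution.
#'
#' @slot pixels numeric matrix, background exactly 0, foreground >= the
#'   levels-remap floor.
#' @slot pixelLinear numeric 3x2 matrix: world offset per (row, col) pixel.
#' @slot pixelOrigin numeric(3): world position (um) of pixel (0, 0).
#' @slot colormap an [AlphaColormap].
#' @slot provenance list: template id and the 2D transform parameters.
#' @export
setClass("PlacedSlice",
  representation(pixels = "matrix", pixelLinear = "matrix",
                 pixelOrigin = "numeric", colormap = "AlphaColormap",
                 provenance = "list"))

setValidity("PlacedSlice", function(object) {
  msg <- character()
  if (!identical(dim(object@pixelLinear), c(3L, 2L)))
    msg <- c(msg, "pixelLinear must be a 3x2 matrix")
  else if (qr(object@pixelLinear)$rank != 2L)
    msg <- c(msg, "pixelLinear must have rank 2 (plane to plane in space)")
  if (length(object@pixelOrigin) != 3L)
    msg <- c(msg, "pixelOrigin must be a world triple (um)")
  if (length(msg)) msg else TRUE
})

#' Seeded recipe for a multimodal phantom
#'
#' Defines a synthetic specimen (ellipsoid/cuboid bodies of distinct
#' densities on a reference canvas) plus everything needed to render the
#' three modalities with known ground truth: the LM grid and its true
#' world transform, per-slice jitter, a declared-vs-true slice thickness
#' pair, and the TEM crop recipe.
#'
#' @slot seed integer; all generators are pure functions of the spec.
#' @slot canvas reference-frame [ImageGrid].
#' @slot bodies list of lists with fields `shape` ("ellipsoid"/"cuboid"),
#'   `center` (um), `semiAxes` (um), `density` in \[0, 1\], `label`, `name`.
#' @slot textureAmp numeric; amplitude of band-limited texture.
#' @slot noiseSigma named numeric: gray-level noise per modality
#'   (`microct`, `lm`, `tem`).
#' @slot lmGrid the LM stack's [ImageGrid] (declared spacing).
#' @slot lmTruth ground-truth [AffineTransform3D], LM world -> canvas world.
#' @slot perSliceJitterSigma numeric, um; random-walk in-plane drift step.
#' @slot sliceThickness numeric(2): (declared, true) slice thickness, um.
#' @slot temSliceIndex integer, 0-based LM slice for TEM re-sectioning.
#' @slot temRoi integer(4): (row0, col0, height, width) crop in LM voxels.
#' @slot temPixelSize numeric, um; TEM pixel size.
#' @slot temTruth ground-truth [SimilarityTransform2D].
#' @export
setClass("PhantomSpec",
  representation(seed = "integer", canvas = "ImageGrid", bodies = "list",
                 textureAmp = "numeric", noiseSigma = "numeric",
                 lmGrid = "ImageGrid", lmTruth = "AffineTransform3D",
                 perSliceJitterSigma = "numeric", sliceThickness = "numeric",
                 temSliceIndex = "integer", temRoi = "integer",
                 temPixelSize = "numeric", temTruth = "SimilarityTransform2D"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!length(object@bodies)) msg <- c(msg, "bodies must be non-empty")
  for (b in object@bodies) {
    need <- c("shape", "center", "semiAxes", "density", "label", "name")
    if (!all(need %in% names(b))) {
      msg <- c(msg, "each body needs shape, center, semiAxes, density, label, name")
      break
    }
    if (b$density < 0 || b$density > 1)
      msg <- c(msg, "body density must lie in [0, 1]")
  }
  dens <- vapply(object@bodies, function(b) b$density, numeric(1))
  labs <- vapply(object@bodies, function(b) as.integer(b$label), integer(1))
  if (length(unique(labs)) > 1L) {
    byLab <- tapply(dens, labs, mean)
    if (length(byLab) > 1L && min(dist(byLab)) < 0.1)
      msg <- c(msg, "densities of distinguishable body classes must differ by >= 0.1")
  }
  if (length(object@sliceThickness) != 2L || any(object@sliceThickness <= 0))
    msg <- c(msg, "sliceThickness must be a positive (declared, true) pair")
  if (length(object@temRoi) != 4L || any(object@temRoi[1:2] < 0L) ||
      any(object@temRoi[3:4] < 1L))
    msg <- c(msg, "temRoi must be (row0, col0, height, width), offsets >= 0")
  if (object@perSliceJitterSigma < 0)
    msg <- c(msg, "perSliceJitterSigma must be >= 0")
  if (length(msg)) msg else TRUE
})
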