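#' @include AllClasses.R
NULL

#' Compose two transforms
#'
#' Returns the transform applying `inner` first, then `outer`:
#' `result(p) = outer(inner(p))`. Both must share the same coordinate
#' convention. The result's mode is the weakest mode that can represent
#' the product (rigid < rigid_iso_scale < rigid_aniso_scale).
#'
#' @param outer,inner transforms of the same class.
#' @return a transform of the common class.
#' @export
setGeneric("compose", function(outer, inner) standardGeneric("compose"))

#' Invert a transform
#'
#' @param x an invertible transform; `compose(x, invert(x))` is the
#'   identity. Mode is preserved.
#' @return the inverse transform.
#' @export
setGeneric("invert", function(x) standardGeneric("invert"))

#' Apply a transform to points
#'
#' @param x a transform.
#' @param points numeric vector of length d or an n x d matrix of
#'   coordinates ((z, y, x) in micrometres for 3D, (row, col) pixels for
#'   2D).
#' @return coordinates of the same shape as `points`.
#' @export
setGeneric("applyTransform", function(x, points) standardGeneric("applyTransform"))

#' @rdname accessors
#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname accessors
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("linearPart", function(x) standardGeneric("linearPart"))

#' @rdname accessors
#' @export
setGeneric("translationPart", function(x) standardGeneric("translationPart"))

#' @rdname accessors
#' @export
setGeneric("transformMode", function(x) standardGeneric("transformMode"))

#' @rdname accessors
#' @export
setGeneric("registeredTransform", function(x) standardGeneric("registeredTransform"))

#' @rdname accessors
#' @export
setGeneric("finalMetric", function(x) standardGeneric("finalMetric"))

#' @rdname accessors
#' @export
setGeneric("metricTrace", function(x) standardGeneric("metricTrace"))

#' @rdname accessors
#' @export
setGeneric("hasConverged", function(x) standardGeneric("hasConverged"))

#' @rdname accessors
#' @export
setGeneric("opacityTable", function(x) standardGeneric("opacityTable"))
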