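#' @include AllClasses.R AllGenerics.R
NULL

.MODE_ORDER <- c(rigid = 1L, rigid_iso_scale = 2L, rigid_aniso_scale = 3L)

#' Construct an affine 3D transform
#'
#' @param linear numeric 3x3 matrix.
#' @param translation numeric(3) in micrometres.
#' @param mode `"rigid"`, `"rigid_iso_scale"` or `"rigid_aniso_scale"`;
#'   invariants of the mode are enforced on construction.
#' @return an [AffineTransform3D-class].
#' @seealso [eulerTransform3D()] for the rotation/scale parameterization,
#'   [compose()], [invert()], [applyTransform()].
#' @export
AffineTransform3D <- function(linear = diag(3), translation = c(0, 0, 0),
                              mode = "rigid_aniso_scale") {
  new("AffineTransform3D", linear = linear,
      translation = as.numeric(translation), mode = mode)
}

#' Identity transform
#' @param mode transform mode tag of the returned identity.
#' @return an [AffineTransform3D-class] that maps every point to itself.
#' @export
identityTransform3D <- function(mode = "rigid") {
  AffineTransform3D(diag(3), c(0, 0, 0), mode)
}

#' Pure translation
#' @param translation numeric(3) shift in micrometres (z, y, x).
#' @return a rigid [AffineTransform3D-class].
#' @export
translationTransform3D <- function(translation) {
  AffineTransform3D(diag(3), translation, "rigid")
}

## Rotation matrices act on (z, y, x) coordinate triples.
## Rz rotates within the section (x-y) plane; Ry mixes (z, x); Rx mixes (z, y).
rotZ <- function(a) matrix(c(1, 0, 0,
                             0, cos(a), sin(a),
                             0, -sin(a), cos(a)), 3, 3)
rotY <- function(b) matrix(c(cos(b), 0, -sin(b),
                             0, 1, 0,
                             sin(b), 0, cos(b)), 3, 3)
rotX <- function(g) matrix(c(cos(g), sin(g), 0,
                             -sin(g), cos(g), 0,
                             0, 0, 1), 3, 3)

#' Rotation matrix from intrinsic Euler angles
#'
#' `R = Rz(angles[1]) %*% Ry(angles[2]) %*% Rx(angles[3])` acting on
#' (z, y, x) triples; `Rz` is the in-section-plane rotation.
#'
#' @param angles numeric(3) radians, (about z, about y, about x).
#' @return 3x3 rotation matrix.
#' @export
rotationMatrixZYX <- function(angles) {
  rotZ(angles[1]) %*% rotY(angles[2]) %*% rotX(angles[3])
}

#' Euler angles of a rotation matrix
#'
#' Inverse of [rotationMatrixZYX()]; unique for |angle about y| < 90 deg.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric(3) radians (about z, about y, about x).
#' @export
eulerAnglesZYX <- function(R) {
  sb <- max(-1, min(1, R[1, 3]))
  b <- asin(sb)
  if (abs(abs(sb) - 1) < 1e-12) {
    # gimbal lock: split arbitrarily, put everything into the z angle
    a <- atan2(R[3, 2], R[2, 2])
    g <- 0
  } else {
    g <- atan2(-R[1, 2], R[1, 1])
    a <- atan2(-R[2, 3], R[3, 3])
  }
  c(a, b, g)
}

#' Transform from rotation, translation and scale about a pivot
#'
#' Builds the map \eqn{p \mapsto R S (p - c) + c + t} with `R` the Euler
#' rotation, `S = diag(scales)` and pivot `c` (typically the moving
#' volume's physical center, which keeps rotation and translation
#' parameters well scaled during optimization).
#'
#' @param angles numeric(3) radians, see [rotationMatrixZYX()].
#' @param translation numeric(3) micrometres.
#' @param scales scalar or numeric(3) per-axis scale factors.
#' @param center numeric(3) pivot in world micrometres.
#' @param mode transform mode; by default derived from `scales`.
#' @return an [AffineTransform3D-class].
#' @export
eulerTransform3D <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                             scales = 1, center = c(0, 0, 0), mode = NULL) {
  scales <- rep(as.numeric(scales), length.out = 3L)
  if (is.null(mode)) {
    mode <- if (all(scales == 1)) "rigid"
            else if (diff(range(scales)) == 0) "rigid_iso_scale"
            else "rigid_aniso_scale"
  }
  L <- rotationMatrixZYX(angles) %*% diag(scales)
  t <- center + translation - as.vector(L %*% center)
  AffineTransform3D(L, t, mode)
}

#' Decompose an affine transform into Euler parameters about a pivot
#'
#' Splits `linear` into `R %*% diag(scales)` (polar-style: per-axis scales
#' are the column norms, valid for transforms built from rotations and
#' axis-aligned scales) and solves for the translation about `center`,
#' inverting [eulerTransform3D()].
#'
#' @param transform an [AffineTransform3D-class].
#' @param center pivot used for the decomposition (um).
#' @return list with `angles` (radians), `translation` (um), `scales`.
#' @export
decomposeAffine3D <- function(transform, center = c(0, 0, 0)) {
  L <- transform@linear
  s <- sqrt(colSums(L^2))
  R <- L %*% diag(1 / s)
  if (det(R) < 0) { # left-handed: flip one axis into the scale
    s[1] <- -s[1]
    R[, 1] <- -R[, 1]
  }
  t <- transform@translation - center + as.vector(L %*% center)
  list(angles = eulerAnglesZYX(R), translation = t, scales = s)
}

#' Construct a 2D similarity transform
#'
#' Maps moving (TEM) pixel coordinates to fixed (template) pixel
#' coordinates. The rotation/scale pivot is not stored: operations that
#' need a centered convention (registration, compositing, simulation) all
#' pivot about the moving image's center, so `angle`, `scale` and
#' `translation` are directly comparable between a ground truth and a
#' recovered transform. [applyTransform()] uses pivot (0, 0).
#'
#' @param angle radians.
#' @param scale positive isotropic scale.
#' @param translation numeric(2) in template pixels (row, col).
#' @return a [SimilarityTransform2D-class].
#' @export
SimilarityTransform2D <- function(angle = 0, scale = 1,
                                  translation = c(0, 0)) {
  new("SimilarityTransform2D", angle = angle, scale = scale,
      translation = as.numeric(translation))
}

## 2x2 matrix of a similarity transform, acting on (row, col) pairs
similarityMatrix2D <- function(x) {
  x@scale * matrix(c(cos(x@angle), sin(x@angle),
                     -sin(x@angle), cos(x@angle)), 2, 2)
}

#' @rdname accessors
#' @export
setMethod("linearPart", "AffineTransform3D", function(x) x@linear)
#' @rdname accessors
#' @export
setMethod("translationPart", "AffineTransform3D", function(x) x@translation)
#' @rdname accessors
#' @export
setMethod("transformMode", "AffineTransform3D", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("linearPart", "SimilarityTransform2D", function(x) similarityMatrix2D(x))
#' @rdname accessors
#' @export
setMethod("translationPart", "SimilarityTransform2D", function(x) x@translation)

#' @rdname compose
#' @export
setMethod("compose", signature("AffineTransform3D", "AffineTransform3D"),
  function(outer, inner) {
    stopifnot(identical(outer@convention, inner@convention))
    mode <- names(.MODE_ORDER)[max(.MODE_ORDER[outer@mode],
                                   .MODE_ORDER[inner@mode])]
    AffineTransform3D(outer@linear %*% inner@linear,
                      as.vector(outer@linear %*% inner@translation) +
                        outer@translation, mode)
  })

#' @rdname invert
#' @export
setMethod("invert", "AffineTransform3D", function(x) {
  Li <- tryCatch(solve(x@linear), error = function(e)
    stop("degenerate transform: linear part is not invertible"))
  AffineTransform3D(Li, -as.vector(Li %*% x@translation), x@mode)
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("AffineTransform3D", "ANY"),
  function(x, points) {
    if (is.matrix(points))
      sweep(points %*% t(x@linear), 2L, x@translation, "+")
    else as.vector(x@linear %*% points) + x@translation
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("SimilarityTransform2D", "ANY"),
  function(x, points) {
    M <- similarityMatrix2D(x)
    if (is.matrix(points))
      sweep(points %*% t(M), 2L, x@translation, "+")
    else as.vector(M %*% points) + x@translation
  })

## full in-plane map of a similarity transform about a pivot:
## q = s R (p - c) + c + t; returns list(M, offset) with q = M p + offset
similarityAbout <- function(x, center) {
  M <- similarityMatrix2D(x)
  list(M = M, offset = center + x@translation - as.vector(M %*% center))
}

setMethod("show", "AffineTransform3D", function(object) {
  d <- decomposeAffine3D(object)
  cat(sprintf("AffineTransform3D [%s], moving world -> fixed world\n",
              object@mode))
  cat(sprintf("  rotation (z,y,x): %s deg; scales: %s\n",
              paste(signif(d$angles * 180 / pi, 4), collapse = ", "),
              paste(signif(d$scales, 5), collapse = ", ")))
  cat(sprintf("  translation: %s um\n",
              paste(signif(object@translation, 5), collapse = ", ")))
})

setMethod("show", "SimilarityTransform2D", function(object) {
  cat(sprintf(
    "SimilarityTransform2D: angle %.4g deg, scale %.5g, shift (%.4g, %.4g) px\n",
    object@angle * 180 / pi, object@scale,
    object@translation[1], object@translation[2]))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: final metric %.6f, %s, %d accepted steps\n",
              object@finalMetric,
              if (object@converged) "converged" else "NOT converged",
              nrow(object@trace)))
  show(object@transform)
})
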