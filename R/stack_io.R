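#' @include AllClasses.R AllGenerics.R grid.R transforms.R
NULL

## Sidecar metadata: the installed TIFF binding cannot emit resolution
## tags, so grid metadata travels in `<stack>.meta.json` next to the TIFF.
## On read, caller-provided spacing always wins; TIFF-adjacent metadata is
## only used to warn about disagreements (resolution metadata is unreliable
## across microscopy tools).
metaPath <- function(path) paste0(path, ".meta.json")

#' Read a multi-page TIFF stack as a volume
#'
#' Reads an 8-bit (or, with `rescale16 = TRUE`, 16-bit) single-channel
#' multi-page TIFF into a [VolumeImage-class]. Spacing is mandatory and is
#' never guessed from TIFF tags: resolution metadata is too unreliable
#' across tools. If a metadata sidecar written by [writeStack()] is
#' present and disagrees with the caller's spacing by more than 0.1%, a
#' warning is issued; the caller's value always wins.
#'
#' @param path multi-page grayscale TIFF file.
#' @param spacing numeric(3) voxel size (sz, sy, sx) in micrometres;
#'   required.
#' @param modality `"microct"`, `"lm"` or `"other"`.
#' @param origin numeric(3) world origin (um), default (0, 0, 0).
#' @param rescale16 set to TRUE to accept 16-bit input and rescale it to
#'   0..255; without the flag 16-bit input is an error.
#' @return a [VolumeImage-class] with grid shape (pages, rows, cols).
#' @export
readStack <- function(path, spacing, modality = "other",
                      origin = c(0, 0, 0), rescale16 = FALSE) {
  if (missing(spacing) || is.null(spacing))
    stop("spacing (um, per axis) is mandatory; it is never guessed from TIFF tags")
  spacing <- as.numeric(spacing)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  if (length(dim(first)) == 3L)
    stop(sprintf("expected single-channel data, got %d channels", dim(first)[3]))
  bits <- attr(first, "bits.per.sample")
  if (!is.null(bits) && bits > 8L) {
    if (!rescale16)
      stop(sprintf("%d-bit input requires rescale16 = TRUE", bits))
    pages <- lapply(pages, function(p) floor(p / (2^bits / 256)))
  }
  vox <- array(0, dim = c(length(pages), nrow(first), ncol(first)))
  for (k in seq_along(pages)) vox[k, , ] <- pages[[k]]
  mp <- metaPath(path)
  if (file.exists(mp)) {
    meta <- jsonlite::fromJSON(mp)
    if (!is.null(meta$spacing_um) &&
        any(abs(meta$spacing_um - spacing) > 0.001 * spacing))
      warning(sprintf(
        "caller spacing (%s) overrides stored metadata spacing (%s)",
        paste(spacing, collapse = ", "),
        paste(meta$spacing_um, collapse = ", ")))
  }
  VolumeImage(vox, ImageGrid(dim(vox), spacing, origin), modality)
}

#' Write a volume as a multi-page TIFF stack
#'
#' Page k holds slice k (z-major). Output is 8-bit grayscale,
#' little-endian, uncompressed by default (`deflate = TRUE` enables
#' deflate compression). Grid metadata (spacing, origin, modality) is
#' recorded in a JSON sidecar `<path>.meta.json`.
#'
#' @param volume a [VolumeImage-class].
#' @param path output TIFF path; the parent directory must exist.
#' @param deflate logical; compress with deflate.
#' @return `path`, invisibly.
#' @export
writeStack <- function(volume, path, deflate = FALSE) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  vox <- round(volume@voxels)
  pages <- lapply(seq_len(dim(vox)[1]), function(k)
    matrix(vox[k, , ] / 255, dim(vox)[2], dim(vox)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                  compression = if (deflate) "deflate" else "none")
  jsonlite::write_json(
    list(format_version = "1.0",
         spacing_um = volume@grid@spacing,
         origin_um = volume@grid@origin,
         shape = volume@grid@shape,
         modality = volume@modality),
    metaPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read the spacing metadata sidecar of a written stack
#'
#' @param path the TIFF path passed to [writeStack()].
#' @return list with `spacing_um`, `origin_um`, `shape`, `modality`, or
#'   NULL if no sidecar exists.
#' @export
readStackMetadata <- function(path) {
  mp <- metaPath(path)
  if (!file.exists(mp)) return(NULL)
  jsonlite::fromJSON(mp)
}

#' Read a 2D grayscale image (TIFF or PNG)
#'
#' @param path image file; format chosen by extension.
#' @return numeric matrix of 8-bit gray values.
#' @export
readImage2D <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") round(png::readPNG(path) * 255)
         else tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L)
    stop(sprintf("expected single-channel data, got %d channels", dim(img)[3]))
  storage.mode(img) <- "double"
  img
}

#' Write a 2D grayscale image (TIFF or PNG)
#'
#' @param image numeric matrix of gray values in 0..255.
#' @param path output file; format chosen by extension (.png or .tif).
#' @return `path`, invisibly.
#' @export
writeImage2D <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  norm <- round(image) / 255
  if (ext == "png") png::writePNG(norm, path)
  else tiff::writeTIFF(norm, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Serialize a 3D transform to JSON
#'
#' Writes the homogeneous 4x4 matrix (row-major, micrometres) together
#' with the convention string, the mode and free-text provenance; the
#' file-based replacement for interactively copy/pasting transform
#' parameters between datasets.
#'
#' @param transform an [AffineTransform3D-class].
#' @param path output JSON path.
#' @param provenance free text recording which registration produced the
#'   transform.
#' @return `path`, invisibly.
#' @export
writeTransform <- function(transform, path, provenance = "") {
  H <- rbind(cbind(transform@linear, transform@translation), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(format_version = "1.0",
         convention = transform@convention,
         mode = transform@mode,
         provenance = provenance,
         matrix = H),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a 3D transform from JSON
#'
#' @param path a JSON file written by [writeTransform()].
#' @return the [AffineTransform3D-class]; round trips are lossless.
#' @export
readTransform <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("malformed transform JSON: ",
                                           conditionMessage(e)))
  if (is.null(doc$matrix) || is.null(doc$convention))
    stop("malformed transform JSON: missing 'matrix' or 'convention'")
  if (!identical(doc$convention, "moving_world_to_fixed_world"))
    stop("unsupported transform convention: ", doc$convention)
  H <- doc$matrix   # fromJSON parses nested arrays into a row-major matrix
  if (!is.matrix(H) || !identical(dim(H), c(4L, 4L)))
    stop("malformed transform JSON: matrix must be 4x4")
  if (max(abs(H[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("not an affine transform: last row must be (0, 0, 0, 1)")
  AffineTransform3D(H[1:3, 1:3], H[1:3, 4],
                    if (is.null(doc$mode)) "rigid_aniso_scale" else doc$mode)
}

sceneKeyOrder <- c("kind", "path", "spacing_um", "origin_um",
                   "transform_file", "pixel_linear", "pixel_origin",
                   "display")

canonicalEntry <- function(e) {
  e <- e[intersect(sceneKeyOrder, names(e))]
  if (!is.null(e$display))
    e$display <- e$display[order(names(e$display))]
  e
}

#' Scene entry constructors
#'
#' Build validated entries for [writeScene()]: a gray `volume`, a `labels`
#' volume, or a `placed_slice` (a 2D image plus its analytic pixel-to-world
#' map).
#'
#' @param path file path of the dataset (TIFF stack or 2D image).
#' @param spacing,origin grid parameters of a volume entry (um).
#' @param transformFile optional path of the transform JSON placing the
#'   volume in the scene.
#' @param colormap display hint, e.g. `"gray"` or `"tem_alpha"`.
#' @param opacityScale display hint in \[0, 1\].
#' @param placed a [PlacedSlice-class] supplying the 2D-to-3D placement.
#' @return a named list usable as a scene entry.
#' @export
sceneVolume <- function(path, spacing, origin = c(0, 0, 0),
                        transformFile = NULL, colormap = "gray",
                        opacityScale = 1) {
  e <- list(kind = "volume", path = path, spacing_um = as.numeric(spacing),
            origin_um = as.numeric(origin),
            display = list(colormap = colormap,
                           opacity_scale = opacityScale))
  if (!is.null(transformFile)) e$transform_file <- transformFile
  canonicalEntry(e)
}

#' @rdname sceneVolume
#' @export
sceneLabels <- function(path, spacing, origin = c(0, 0, 0),
                        transformFile = NULL, colormap = "labels",
                        opacityScale = 1) {
  e <- sceneVolume(path, spacing, origin, transformFile, colormap,
                   opacityScale)
  e$kind <- "labels"
  canonicalEntry(e)
}

#' @rdname sceneVolume
#' @export
scenePlacedSlice <- function(path, placed, colormap = "tem_alpha") {
  canonicalEntry(list(
    kind = "placed_slice", path = path,
    pixel_linear = placed@pixelLinear,
    pixel_origin = placed@pixelOrigin,
    display = list(colormap = colormap, opacity_scale = 1)))
}

#' Write a displayable scene description
#'
#' One JSON file listing every co-registered dataset so all of them can be
#' displayed simultaneously in one 3D scene. Every referenced file must
#' exist (relative paths are resolved against the scene file's directory)
#' and every placed slice must carry a full 2D-to-3D placement. Loading a
#' scene with [readScene()] and re-saving it is byte-identical.
#'
#' @param entries list of entries from [sceneVolume()], [sceneLabels()],
#'   [scenePlacedSlice()] (or a structure returned by [readScene()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeScene <- function(entries, path) {
  if (!is.null(entries$entries)) entries <- entries$entries
  base <- dirname(path)
  for (e in entries) {
    ref <- e$path
    full <- if (grepl("^(/|[A-Za-z]:)", ref)) ref else file.path(base, ref)
    if (!file.exists(full))
      stop("scene references a missing file: ", ref)
    if (identical(e$kind, "placed_slice") &&
        (is.null(e$pixel_linear) || is.null(e$pixel_origin)))
      stop("placed_slice entry lacks a 2D-to-3D placement")
  }
  entries <- lapply(entries, canonicalEntry)
  jsonlite::write_json(list(format_version = "1.0", entries = entries),
                       path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Serialize a slice template (image + placement sidecar)
#'
#' Writes the template pixels as a 2D TIFF/PNG plus a JSON sidecar
#' carrying everything needed to restore its 3D placement: pixel size,
#' slice index, crop offset, the source grid and the registered stack's
#' transform.
#'
#' @param template a [SliceTemplate-class].
#' @param path image output path (.tif or .png).
#' @return `path`, invisibly.
#' @export
writeTemplate <- function(template, path) {
  writeImage2D(template@pixels, path)
  H <- rbind(cbind(template@sourceTransform@linear,
                   template@sourceTransform@translation), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(format_version = "1.0",
         pixel_size_um = template@pixelSize,
         slice_index = template@sliceIndex,
         crop_offset = template@cropOffset,
         source_grid = list(shape = template@sourceGrid@shape,
                            spacing_um = template@sourceGrid@spacing,
                            origin_um = template@sourceGrid@origin),
         source_transform = list(matrix = H,
                                 mode = template@sourceTransform@mode)),
    metaPath(path), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a slice template written by [writeTemplate()]
#'
#' @param path the image path passed to [writeTemplate()].
#' @return the restored [SliceTemplate-class].
#' @export
readTemplate <- function(path) {
  px <- readImage2D(path)
  meta <- jsonlite::fromJSON(metaPath(path))
  H <- meta$source_transform$matrix
  new("SliceTemplate", pixels = px,
      pixelSize = as.numeric(meta$pixel_size_um),
      sliceIndex = as.integer(meta$slice_index),
      cropOffset = as.numeric(meta$crop_offset),
      sourceTransform = AffineTransform3D(H[1:3, 1:3], H[1:3, 4],
                                          meta$source_transform$mode),
      sourceGrid = ImageGrid(meta$source_grid$shape,
                             meta$source_grid$spacing_um,
                             meta$source_grid$origin_um))
}

#' Serialize a placed slice (composited image + placement sidecar)
#'
#' @param placed a [PlacedSlice-class].
#' @param path image output path (.tif or .png).
#' @return `path`, invisibly.
#' @export
writePlacedSlice <- function(placed, path) {
  writeImage2D(placed@pixels, path)
  jsonlite::write_json(
    list(format_version = "1.0",
         pixel_linear = placed@pixelLinear,
         pixel_origin = placed@pixelOrigin,
         colormap = "tem_alpha",
         provenance = placed@provenance),
    metaPath(path), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a placed slice written by [writePlacedSlice()]
#'
#' @param path the image path passed to [writePlacedSlice()].
#' @return the restored [PlacedSlice-class].
#' @export
readPlacedSlice <- function(path) {
  px <- readImage2D(path)
  meta <- jsonlite::fromJSON(metaPath(path))
  new("PlacedSlice", pixels = px,
      pixelLinear = matrix(meta$pixel_linear, 3, 2),
      pixelOrigin = as.numeric(meta$pixel_origin),
      colormap = temAlphaColormap(),
      provenance = as.list(meta$provenance))
}

#' Read a scene description
#'
#' @param path a JSON file written by [writeScene()].
#' @return list with `format_version` and `entries`.
#' @export
readScene <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$entries <- lapply(doc$entries, function(e) {
    for (f in c("spacing_um", "origin_um", "pixel_origin"))
      if (!is.null(e[[f]])) e[[f]] <- as.numeric(unlist(e[[f]]))
    if (!is.null(e$pixel_linear))
      e$pixel_linear <- matrix(unlist(e$pixel_linear), nrow = 3, byrow = TRUE)
    if (!is.null(e$display))
      e$display <- lapply(e$display, function(v) unlist(v))
    canonicalEntry(e)
  })
  doc
}
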