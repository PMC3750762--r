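#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an opacity colormap
#'
#' @param opacity integer(256) opacity per 8-bit gray value.
#' @return an [AlphaColormap-class].
#' @export
AlphaColormap <- function(opacity) {
  new("AlphaColormap", opacity = as.integer(opacity))
}

#' Transparency colormap for embedded TEM slices
#'
#' The display lookup table that makes the black background of a
#' composited TEM slice fully transparent while keeping every remapped
#' foreground pixel fully visible: opacity 0 for gray values 0-9 and
#' opacity 255 for gray values 10-255. The threshold matches the
#' levels-remap floor of [levelsRemap()], which guarantees foreground
#' pixels never fall below gray 10.
#'
#' @return an [AlphaColormap-class] with a single step between gray 9
#'   and 10.
#' @examples
#' cm <- temAlphaColormap()
#' opacityTable(cm)[c(1, 10, 11, 256)]  # gray 0, 9, 10, 255
#' @export
temAlphaColormap <- function() {
  AlphaColormap(c(rep(0L, 10), rep(255L, 246)))
}

setMethod("show", "AlphaColormap", function(object) {
  op <- object@opacity
  cat(sprintf("AlphaColormap: 256 entries, %d transparent, %d opaque\n",
              sum(op == 0L), sum(op == 255L)))
})
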