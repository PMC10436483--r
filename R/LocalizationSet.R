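#' Create a LocalizationSet
#'
#' @param coords Numeric `n x d` matrix (or data.frame) of coordinates in
#'   nanometers, `d` = 2 or 3.
#' @param bounds Optional `2 x d` box from [boundingBox()]; defaults to the
#'   tight axis-aligned box of the data.  A user-supplied box may be larger
#'   than the data extent, never smaller.
#' @param extras Optional `data.frame` of per-localization columns.
#' @param metadata Optional named list.
#' @return A [LocalizationSet-class].
#' @export
#' @examples
#' locs <- LocalizationSet(cbind(runif(10), runif(10), runif(10)) * 100)
#' nLocs(locs)
LocalizationSet <- function(coords, bounds = NULL, extras = NULL,
                            metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  vcAssert(nrow(coords) >= 1L, "need at least one localization", "empty_input")
  vcAssert(ncol(coords) %in% 2:3, "coordinates must be 2D or 3D", "input")
  vcAssert(all(is.finite(coords)), "all coordinates must be finite", "input")
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  if (is.null(bounds)) bounds <- tightBox(coords)
  checkBox(bounds, ncol(coords))
  if (is.null(extras)) extras <- data.frame(row.names = seq_len(nrow(coords)))
  new("LocalizationSet", coords = coords, bounds = bounds,
      extras = as.data.frame(extras), metadata = metadata)
}

#' @rdname LocalizationSet
#' @export
setMethod("locCoords", "LocalizationSet", function(object) object@coords)

#' @rdname LocalizationSet
#' @export
setMethod("nLocs", "LocalizationSet", function(object) nrow(object@coords))

#' @rdname LocalizationSet
#' @export
setMethod("locBounds", "LocalizationSet", function(object) object@bounds)

#' @rdname LocalizationSet
#' @export
setMethod("locDim", "LocalizationSet", function(object) ncol(object@coords))

#' @rdname LocalizationSet
#' @export
setMethod("locExtras", "LocalizationSet", function(object) object@extras)

setMethod("show", "LocalizationSet", function(object) {
  d <- locDim(object)
  ext <- object@bounds[2L, ] - object@bounds[1L, ]
  cat(sprintf("LocalizationSet: %d localizations in %dD\n", nLocs(object), d))
  cat(sprintf("  bounds extent (nm): %s\n",
              paste(sprintf("%.1f", ext), collapse = " x ")))
  if (ncol(object@extras) > 0L)
    cat("  extras:", paste(colnames(object@extras), collapse = ", "), "\n")
})
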