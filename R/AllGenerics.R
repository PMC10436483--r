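#' @rdname LocalizationSet
#' @param object,x An object.
#' @export
setGeneric("locCoords", function(object) standardGeneric("locCoords"))

#' @rdname LocalizationSet
#' @export
setGeneric("nLocs", function(object) standardGeneric("nLocs"))

#' @rdname LocalizationSet
#' @export
setGeneric("locBounds", function(object) standardGeneric("locBounds"))

#' @rdname LocalizationSet
#' @export
setGeneric("locDim", function(object) standardGeneric("locDim"))

#' @rdname LocalizationSet
#' @export
setGeneric("locExtras", function(object) standardGeneric("locExtras"))

#' @rdname buildDelaunay
#' @export
setGeneric("simplices", function(object) standardGeneric("simplices"))

#' @rdname buildDelaunay
#' @export
setGeneric("oneRing", function(object) standardGeneric("oneRing"))

#' @rdname buildVoronoi
#' @export
setGeneric("cellSizes", function(object) standardGeneric("cellSizes"))

#' @rdname buildVoronoi
#' @export
setGeneric("isBorder", function(object) standardGeneric("isBorder"))

#' @rdname buildVoronoi
#' @export
setGeneric("meanCellSize", function(object) standardGeneric("meanCellSize"))

#' Evaluate a null model's density at normalized sizes
#' @param object A null model.
#' @param y Nonnegative normalized cell sizes.
#' @return Density values at `y`.
#' @export
setGeneric("nullDensity", function(object, y) standardGeneric("nullDensity"))
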