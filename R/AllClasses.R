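#' LocalizationSet: a table of molecular localizations
#'
#' The universal input container: an `n x d` coordinate matrix in
#' nanometers (d = 2 or 3), an axis-aligned bounding volume that contains
#' every coordinate, optional per-localization columns (frame, intensity,
#' uncertainty, ground-truth label, ...), and free-form metadata.
#'
#' @slot coords Numeric `n x d` matrix, nanometers.
#' @slot bounds `2 x d` matrix (rows `lo`, `hi`); may be user-supplied and
#'   larger than the data extent, never smaller.
#' @slot extras `data.frame` with `n` rows (possibly zero columns).
#' @slot metadata Named list (simulation ground truth, provenance, ...).
#' @seealso [LocalizationSet()], [readLocalizations()]
#' @exportClass LocalizationSet
setClass("LocalizationSet",
         representation(coords = "matrix", bounds = "matrix",
                        extras = "data.frame", metadata = "list"))

setValidity("LocalizationSet", function(object) {
  co <- object@coords
  if (!is.numeric(co) || nrow(co) < 1L) return("need at least one localization")
  if (!ncol(co) %in% 2:3) return("coordinates must be 2D or 3D")
  if (!all(is.finite(co))) return("all coordinates must be finite")
  b <- object@bounds
  if (!is.matrix(b) || nrow(b) != 2L || ncol(b) != ncol(co))
    return("bounds must be a 2 x dim matrix")
  if (any(b[2L, ] <= b[1L, ])) return("bounds must have positive extent")
  lo <- apply(co, 2L, min); hi <- apply(co, 2L, max)
  if (any(lo < b[1L, ]) || any(hi > b[2L, ]))
    return("bounds must contain every coordinate")
  if (nrow(object@extras) > 0L && nrow(object@extras) != nrow(co))
    return("extras must have one row per localization")
  TRUE
})

#' DelaunayComplex: simplices and one-ring adjacency
#'
#' The Delaunay triangulation of a (deduplicated) localization set, stored
#' as its simplex list plus the one-ring adjacency in compressed sparse row
#' form.  The one-ring of a point -- all points sharing a simplex with it --
#' is exactly the set of its Voronoi facet neighbours, which is what the
#' cell construction consumes.
#'
#' @slot points The originating [LocalizationSet-class].
#' @slot keep Integer indices of the retained (first-occurrence) rows after
#'   exact-duplicate merging.
#' @slot dupMap Integer vector mapping every original row to its
#'   deduplicated generator index (1..length(keep)).
#' @slot simplices Integer `m x (d+1)` matrix of generator indices.
#' @slot ringStart,ringIdx CSR encoding of the one-ring adjacency.
#' @slot joggled Logical: whether a deterministic joggle retry was needed to
#'   resolve a near-degenerate configuration.
#' @exportClass DelaunayComplex
setClass("DelaunayComplex",
         representation(points = "LocalizationSet", keep = "integer",
                        dupMap = "integer", simplices = "matrix",
                        ringStart = "integer", ringIdx = "integer",
                        joggled = "logical"))

#' VoronoiCell: one explicitly constructed Voronoi cell
#'
#' @slot index Generator index (into the deduplicated set), or `NA` for
#'   free-standing cells built from explicit neighbour coordinates.
#' @slot size Cell measure: nm^2 (2D) or nm^3 (3D); always positive.
#' @slot isBorder TRUE when the cell is cut by the clip box or reaches
#'   outside the dataset bounding volume.
#' @slot neighbors Indices (or row numbers of the supplied neighbour matrix)
#'   whose bisector contributes a facet.
#' @slot polytope List with `vertices` (matrix) and, in 3D, `faces` (list of
#'   vertex-index loops); in 2D the vertices form the polygon loop.
#' @exportClass VoronoiCell
setClass("VoronoiCell",
         representation(index = "integer", size = "numeric",
                        isBorder = "logical", neighbors = "integer",
                        polytope = "list"))

setValidity("VoronoiCell", function(object) {
  if (length(object@size) != 1L || !is.finite(object@size) ||
      object@size <= 0) return("cell size must be a positive scalar")
  TRUE
})

#' VoronoiDiagram: per-point cell sizes, border flags and adjacency
#'
#' One Voronoi cell per deduplicated localization, built independently by
#' bisector clipping against the one-ring neighbours and the clip box.
#' Cells are clipped to `clipBounds`; `border` flags cells cut by the clip
#' box or reaching outside `dataBounds` (the dataset bounding volume), and
#' such cells are excluded from all statistics downstream.
#'
#' @slot delaunay The [DelaunayComplex-class] the cells were built from.
#' @slot sizes Numeric vector of cell measures (nm^2 or nm^3).
#' @slot border Logical border flags.
#' @slot nFacets Integer count of neighbour-contributed facets per cell.
#' @slot clipBounds,dataBounds `2 x d` boxes; `clipBounds` contains
#'   `dataBounds`.
#' @exportClass VoronoiDiagram
setClass("VoronoiDiagram",
         representation(delaunay = "DelaunayComplex", sizes = "numeric",
                        border = "logical", nFacets = "integer",
                        clipBounds = "matrix", dataBounds = "matrix"))

setValidity("VoronoiDiagram", function(object) {
  n <- length(object@sizes)
  if (length(object@border) != n || length(object@nFacets) != n)
    return("sizes, border and nFacets must have equal length")
  if (any(object@sizes <= 0)) return("cell sizes must be positive")
  TRUE
})

#' CellSizePDF: a binned, density-normalized cell-size distribution
#'
#' Histogram density of normalized cell sizes \eqn{y = S/\langle S\rangle}
#' on fixed bins.  Values above the last edge are dropped and accounted in
#' `droppedMass`, so that `sum(density * diff(breaks)) + droppedMass == 1`.
#'
#' @slot breaks Increasing bin edges (dimensionless normalized sizes).
#' @slot density Nonnegative density per bin.
#' @slot nSamples Number of cells that entered the histogram denominator.
#' @slot meanSize The mean cell size used for normalization (nm^2/nm^3), or
#'   `NA` when the sample was normalized upstream.
#' @slot droppedMass Fraction of the sample above the last edge.
#' @exportClass CellSizePDF
setClass("CellSizePDF",
         representation(breaks = "numeric", density = "numeric",
                        nSamples = "integer", meanSize = "numeric",
                        droppedMass = "numeric"))

setValidity("CellSizePDF", function(object) {
  if (is.unsorted(object@breaks, strictly = TRUE))
    return("breaks must be strictly increasing")
  if (length(object@density) != length(object@breaks) - 1L)
    return("density must have one value per bin")
  if (any(object@density < 0)) return("density must be nonnegative")
  tot <- sum(object@density * diff(object@breaks)) + object@droppedMass
  if (abs(tot - 1) > 1e-6) return("density must integrate to 1")
  TRUE
})

#' MonteCarloNull: Monte-Carlo null model with envelope
#'
#' Cell-size distributions of repeated uniform (complete spatial
#' randomness) simulations with the same number of localizations and the
#' same bounding volume as the data: the per-simulation densities, their
#' bin-wise mean, and a bin-wise envelope (pointwise min/max by default,
#' optionally quantiles).
#'
#' @slot breaks Shared bin edges.
#' @slot perSim `nbins x nSims` matrix of per-simulation densities.
#' @slot meanDensity,lower,upper Bin-wise mean and envelope.
#' @slot nSims,seed,nPoints Simulation bookkeeping.
#' @slot bounds The simulated bounding volume.
#' @slot envelopeQuantiles Numeric length-2 quantiles, or empty for min/max.
#' @exportClass MonteCarloNull
setClass("MonteCarloNull",
         representation(breaks = "numeric", perSim = "matrix",
                        meanDensity = "numeric", lower = "numeric",
                        upper = "numeric", nSims = "integer", seed = "integer",
                        nPoints = "integer", bounds = "matrix",
                        envelopeQuantiles = "numeric"))

setValidity("MonteCarloNull", function(object) {
  nb <- length(object@breaks) - 1L
  if (nrow(object@perSim) != nb) return("perSim must have one row per bin")
  if (length(object@meanDensity) != nb || length(object@lower) != nb ||
      length(object@upper) != nb) return("mean/envelope must match bins")
  if (any(object@lower > object@meanDensity + 1e-12) ||
      any(object@upper < object@meanDensity - 1e-12))
    return("envelope must contain the mean density bin-wise")
  TRUE
})

#' AnalyticalNull: closed-form Poisson-Voronoi gamma null
#'
#' The fixed two-parameter gamma approximations of the normalized
#' Poisson-Voronoi cell-size distribution: shape 7/2 and rate 7/2 in 2D,
#' shape 5 and rate 5 in 3D.  Both integrate to one and have unit mean by
#' construction.
#'
#' @slot dim 2 or 3.
#' @slot shape,rate Gamma parameters of the normalized-size density.
#' @exportClass AnalyticalNull
setClass("AnalyticalNull",
         representation(dim = "integer", shape = "numeric", rate = "numeric"))

#' VoronoiThreshold: a cell-size selection threshold
#'
#' @slot yStar Threshold on the normalized size axis.
#' @slot sStar Absolute threshold `yStar * meanSize` (nm^2 or nm^3).
#' @slot meanSize The normalizing mean cell size.
#' @slot nullKind `"monte_carlo"` or `"analytical"` (or `"density_factor"`).
#' @exportClass VoronoiThreshold
setClass("VoronoiThreshold",
         representation(yStar = "numeric", sStar = "numeric",
                        meanSize = "numeric", nullKind = "character"))

setValidity("VoronoiThreshold", function(object) {
  if (!is.na(object@yStar) && object@yStar <= 0)
    return("yStar must be positive")
  if (!is.na(object@yStar) && is.finite(object@meanSize) &&
      is.finite(object@sStar) &&
      abs(object@sStar - object@yStar * object@meanSize) >
        1e-9 * abs(object@sStar)) return("sStar must equal yStar * meanSize")
  TRUE
})

#' ClusteringResult: selected cells and connected clusters
#'
#' @slot threshold The [VoronoiThreshold-class] used for selection.
#' @slot selected Logical per (deduplicated) cell.
#' @slot clusters `data.frame` with one row per cluster: `id`, `nLocs`,
#'   `volume` and barycenter coordinates.
#' @slot members List of integer vectors: original localization row indices
#'   per cluster.
#' @slot parameters Provenance record (null configuration, binning,
#'   `minLocs`, seed).
#' @exportClass ClusteringResult
setClass("ClusteringResult",
         representation(threshold = "VoronoiThreshold", selected = "logical",
                        clusters = "data.frame", members = "list",
                        parameters = "list"))
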