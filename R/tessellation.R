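#' Build the Delaunay triangulation of a localization set
#'
#' Exact duplicate positions are merged first (first occurrence kept, with
#' the full mapping recorded), then the triangulation is built with an
#' incremental Bowyer-Watson algorithm using filtered geometric predicates;
#' near-degenerate configurations that defeat the predicates are resolved by
#' a deterministic joggle retry.  The one-ring of every point -- all points
#' sharing a simplex with it -- is returned alongside the simplices; by
#' Voronoi/Delaunay duality it contains exactly the points whose bisectors
#' bound the point's Voronoi cell.
#'
#' @param locs A [LocalizationSet-class] with at least `dim + 1` distinct
#'   points, not all collinear (2D) / coplanar (3D).
#' @return A [DelaunayComplex-class].
#' @seealso [directNeighbors()], [buildVoronoi()]
#' @export
#' @examples
#' locs <- LocalizationSet(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)))
#' dt <- buildDelaunay(locs)
#' simplices(dt)
#' directNeighbors(dt, 1)
buildDelaunay <- function(locs) {
  stopifnot(is(locs, "LocalizationSet"))
  co <- locCoords(locs)
  d <- ncol(co)
  dup <- duplicated(co)
  keep <- which(!dup)
  vcAssert(length(keep) >= d + 1L,
           sprintf("need at least %d distinct points", d + 1L), "input")
  # map each original row to its kept generator
  key <- do.call(paste, c(as.data.frame(co), sep = "\r"))
  dupMap <- match(key, key[keep])
  dedup <- co[keep, , drop = FALSE]
  res <- tryCatch(
    if (d == 3L) .dt3_build(dedup) else .dt2_build(dedup),
    error = function(e) vcStop(conditionMessage(e), "geometry"))
  new("DelaunayComplex", points = locs, keep = as.integer(keep),
      dupMap = as.integer(dupMap), simplices = res$simplices,
      ringStart = as.integer(res$ring_start),
      ringIdx = as.integer(res$ring_idx),
      joggled = res$joggle_attempt > 0L)
}

#' @rdname buildDelaunay
#' @param object A [DelaunayComplex-class].
#' @export
setMethod("simplices", "DelaunayComplex", function(object) object@simplices)

#' @rdname buildDelaunay
#' @export
setMethod("oneRing", "DelaunayComplex", function(object) {
  lapply(seq_len(length(object@ringStart) - 1L),
         function(i) ringOf(object, i))
})

ringOf <- function(dt, i) {
  a <- dt@ringStart[i]
  b <- dt@ringStart[i + 1L] - 1L
  if (b < a) integer() else dt@ringIdx[a:b]
}

nGenerators <- function(dt) length(dt@ringStart) - 1L

#' One-ring (direct Delaunay) neighbours of a point
#'
#' @param dt A [DelaunayComplex-class].
#' @param i Generator index (into the deduplicated point set).
#' @return Sorted integer vector of neighbour indices; never empty for a
#'   triangulated point.
#' @export
directNeighbors <- function(dt, i) {
  stopifnot(is(dt, "DelaunayComplex"))
  vcAssert(length(i) == 1L && !is.na(i) && i >= 1L && i <= nGenerators(dt),
           sprintf("index out of range [1, %d]", nGenerators(dt)), "index")
  ringOf(dt, as.integer(i))
}

setMethod("show", "DelaunayComplex", function(object) {
  cat(sprintf("DelaunayComplex: %d generators, %d simplices (%dD)%s\n",
              nGenerators(object), nrow(object@simplices),
              locDim(object@points),
              if (object@joggled) " [joggled]" else ""))
})

# pseudo-complex with all-pairs neighbourhoods, for point sets too small or
# too degenerate to triangulate
completeComplex <- function(locs) {
  co <- locCoords(locs)
  dup <- duplicated(co)
  keep <- which(!dup)
  key <- do.call(paste, c(as.data.frame(co), sep = "\r"))
  dupMap <- match(key, key[keep])
  m <- length(keep)
  vcAssert(m >= 1L, "need at least one distinct point", "input")
  ring <- lapply(seq_len(m), function(i) setdiff(seq_len(m), i))
  new("DelaunayComplex", points = locs, keep = as.integer(keep),
      dupMap = as.integer(dupMap),
      simplices = matrix(integer(), 0L, ncol(co) + 1L),
      ringStart = as.integer(cumsum(c(1L, lengths(ring)))),
      ringIdx = as.integer(unlist(ring)), joggled = FALSE)
}

resolveClip <- function(clipBounds, dataBounds) {
  if (identical(clipBounds, "auto")) return(expandBox(dataBounds, 0.05))
  checkBox(clipBounds, ncol(dataBounds))
  vcAssert(boxContains(clipBounds, dataBounds, tol = 1e-9),
           "clip bounds must contain the data bounds", "input")
  clipBounds
}

#' Build the Voronoi diagram of a localization set
#'
#' Runs the full per-cell construction: Delaunay triangulation, one-ring
#' gathering, then independent brute-force construction of every cell as
#' the intersection of the bisector half-spaces with its neighbours,
#' clipped to `clipBounds`.  Cells are constructed nearest-neighbour first
#' and construction stops once the remaining bisectors probably cannot cut
#' the cell (a sound distance bound, so results are exact).  Cells cut by
#' the clip box or reaching outside the dataset bounding volume are flagged
#' as border cells; `meanCellSize` is taken over non-border cells only.
#'
#' @param locs A [LocalizationSet-class], or a prebuilt
#'   [DelaunayComplex-class].
#' @param clipBounds `"auto"` (data bounds expanded by 5\% per side, so
#'   that convex-hull cells keep a finite, flagged cell) or an explicit box
#'   containing the data bounds.  Use the data bounds themselves to make
#'   the cells partition the bounding volume exactly.
#' @param polytopes If TRUE, keep every cell's explicit polytope (memory
#'   heavy; intended for small sets).
#' @return A [VoronoiDiagram-class].
#' @export
#' @examples
#' locs <- simulateUniform(200, boundingBox(c(0,0,0), c(1000,1000,1000)), 1)
#' vd <- buildVoronoi(locs)
#' summary(cellSizes(vd))
#' mean(isBorder(vd))
buildVoronoi <- function(locs, clipBounds = "auto", polytopes = FALSE) {
  dt <- if (is(locs, "DelaunayComplex")) locs else tryCatch(
    buildDelaunay(locs),
    vc_input_error = function(e) completeComplex(locs),
    vc_geometry_error = function(e) {
      # affinely degenerate configurations (all collinear/coplanar) still
      # have a well-defined Voronoi diagram: fall back to all-pairs
      # neighbourhoods, which the clipping handles exactly
      if (grepl("degenerate", conditionMessage(e)))
        completeComplex(locs)
      else stop(e)
    })
  dataB <- locBounds(dt@points)
  clip <- resolveClip(clipBounds, dataB)
  co <- locCoords(dt@points)[dt@keep, , drop = FALSE]
  res <- tryCatch(
    .vc_cells(co, dt@ringStart, dt@ringIdx, clip[1L, ], clip[2L, ],
              dataB[1L, ], dataB[2L, ], polytopes, polytopes),
    error = function(e) vcStop(conditionMessage(e), "geometry"))
  vd <- new("VoronoiDiagram", delaunay = dt, sizes = res$sizes,
            border = res$touches_clip | res$outside_data,
            nFacets = as.integer(res$n_facets), clipBounds = clip,
            dataBounds = dataB)
  if (polytopes) attr(vd, "polytopes") <- res$polytopes
  vd
}

#' @rdname buildVoronoi
#' @param object A [VoronoiDiagram-class].
#' @export
setMethod("cellSizes", "VoronoiDiagram", function(object) object@sizes)

#' @rdname buildVoronoi
#' @export
setMethod("isBorder", "VoronoiDiagram", function(object) object@border)

#' @rdname buildVoronoi
#' @export
setMethod("meanCellSize", "VoronoiDiagram",
          function(object) mean(object@sizes[!object@border]))

setMethod("show", "VoronoiDiagram", function(object) {
  d <- locDim(object@delaunay@points)
  cat(sprintf("VoronoiDiagram: %d cells (%dD), %.1f%% border\n",
              length(object@sizes), d, 100 * mean(object@border)))
  cat(sprintf("  mean non-border cell size: %.6g nm^%d\n",
              meanCellSize(object), d))
})

#' Construct a single Voronoi cell from explicit neighbours
#'
#' Builds the cell of point `p` as the intersection of the half-spaces
#' closer to `p` than to each neighbour, intersected with the clip box.
#' With `neighbors` equal to the one-ring this reproduces the diagram cell
#' exactly; with all other points it is the brute-force construction used
#' as an oracle for the duality guarantee.
#'
#' @param locs A [LocalizationSet-class] (or bare coordinate matrix).
#' @param i Index of the generating point.
#' @param neighbors Indices of candidate neighbours (default: all others).
#' @param clipBounds Clip box, or `"auto"` (data bounds + 5\% per side).
#' @return A [VoronoiCell-class] with explicit polytope geometry.
#' @export
constructCell <- function(locs, i, neighbors = NULL, clipBounds = "auto") {
  co <- if (is(locs, "LocalizationSet")) locCoords(locs) else as.matrix(locs)
  dataB <- if (is(locs, "LocalizationSet")) locBounds(locs) else tightBox(co)
  clip <- resolveClip(clipBounds, dataB)
  vcAssert(length(i) == 1L && i >= 1L && i <= nrow(co), "index out of range",
           "index")
  if (is.null(neighbors)) neighbors <- setdiff(seq_len(nrow(co)), i)
  vcAssert(!i %in% neighbors, "a point cannot neighbour itself", "input")
  nb <- co[neighbors, , drop = FALSE]
  res <- tryCatch(
    .vc_cell_single(co[i, ], nb, clip[1L, ], clip[2L, ], dataB[1L, ],
                    dataB[2L, ]),
    error = function(e) vcStop(conditionMessage(e), "geometry"))
  new("VoronoiCell", index = as.integer(i), size = res$size,
      isBorder = res$touches_clip || res$outside_data,
      neighbors = as.integer(neighbors[res$facet_neighbors]),
      polytope = res$polytope)
}

#' Explicit polytope of a Voronoi cell
#'
#' Recomputes cell `i` of a diagram with explicit geometry and returns its
#' convex polytope (vertex coordinates plus, in 3D, faces as vertex-index
#' loops).  The polytope measure agrees with the stored cell size to within
#' 1e-9 relative; a degenerate (flat) cell raises a geometry error.
#'
#' @param vd A [VoronoiDiagram-class].
#' @param i Cell index.
#' @return A list with `vertices`, `faces` (3D) and `size`.
#' @export
cellPolytope <- function(vd, i) {
  stopifnot(is(vd, "VoronoiDiagram"))
  dt <- vd@delaunay
  vcAssert(length(i) == 1L && i >= 1L && i <= length(vd@sizes),
           "index out of range", "index")
  co <- locCoords(dt@points)[dt@keep, , drop = FALSE]
  ring <- ringOf(dt, as.integer(i))
  res <- .vc_cell_single(co[i, ], co[ring, , drop = FALSE],
                         vd@clipBounds[1L, ], vd@clipBounds[2L, ],
                         vd@dataBounds[1L, ], vd@dataBounds[2L, ])
  vcAssert(nrow(res$polytope$vertices) >= ncol(co) + 1L,
           "degenerate (flat) cell", "geometry")
  vcAssert(abs(res$size - vd@sizes[i]) <= 1e-9 * vd@sizes[i],
           "polytope measure disagrees with stored cell size", "geometry")
  c(res$polytope, list(size = res$size))
}

#' Re-flag border cells against a (smaller) bounding volume
#'
#' Marks as border every cell whose polytope reaches outside `bounds`
#' (including all cells cut by the clip box), and leaves interior cells
#' untouched.  Statistics downstream (mean cell size, normalized sizes)
#' then exclude the newly flagged cells.
#'
#' @param vd A [VoronoiDiagram-class] built with `clipBounds` containing
#'   `bounds`.
#' @param bounds The bounding volume to flag against.
#' @return An updated [VoronoiDiagram-class].
#' @export
flagBorderCells <- function(vd, bounds) {
  stopifnot(is(vd, "VoronoiDiagram"))
  checkBox(bounds, ncol(vd@dataBounds))
  vcAssert(boxContains(vd@clipBounds, bounds, tol = 1e-9),
           "diagram clip bounds must contain the flag bounds", "input")
  dt <- vd@delaunay
  co <- locCoords(dt@points)[dt@keep, , drop = FALSE]
  res <- .vc_cells(co, dt@ringStart, dt@ringIdx, vd@clipBounds[1L, ],
                   vd@clipBounds[2L, ], bounds[1L, ], bounds[2L, ],
                   FALSE, FALSE)
  vd@border <- res$touches_clip | res$outside_data
  vd@dataBounds <- bounds
  vd
}

#' Export a Voronoi diagram as a per-cell table
#'
#' Writes one row per cell: generator index, cell size, border flag and the
#' number of neighbour-contributed facets.
#'
#' @param vd A [VoronoiDiagram-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
exportDiagram <- function(vd, path) {
  stopifnot(is(vd, "VoronoiDiagram"))
  df <- data.frame(index = seq_along(vd@sizes), size = vd@sizes,
                   is_border = vd@border, n_neighbors = vd@nFacets)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a 3D cell polytope in OFF format
#'
#' @param poly A polytope as returned by [cellPolytope()] (3D).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeOFF <- function(poly, path) {
  v <- poly$vertices
  vcAssert(ncol(v) == 3L, "OFF export requires a 3D polytope", "input")
  f <- poly$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), length(f)), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(vapply(f, function(loop)
    paste(c(length(loop), loop - 1L), collapse = " "), ""), con)
  invisible(path)
}
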