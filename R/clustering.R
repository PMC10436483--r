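#' Find the segmentation threshold as a distribution intersection
#'
#' Clustered data show an excess of small Voronoi cells over a random null.
#' Scanning the normalized size axis upward from zero, the threshold is the
#' first point where the experimental density, having exceeded the null,
#' crosses back to at-or-below it -- located by linear interpolation
#' between adjacent bin centers.  The null is evaluated at bin centers
#' (analytical form) or on the shared bins (Monte-Carlo mean).  The scan
#' only arms in bins whose observed count exceeds an exact Poisson tail
#' bound under the null, so clusterless data report the no-signal
#' condition rather than a chance crossing; the crossing location itself
#' is unaffected.
#'
#' @param empirical A [CellSizePDF-class] of the experimental data,
#'   carrying the normalizing mean size.
#' @param null An [AnalyticalNull-class] or [MonteCarloNull-class].
#' @return A [VoronoiThreshold-class].  When the experimental density never
#'   exceeds the null (no small-cell excess) a `vc_no_cluster_signal_error`
#'   is raised, distinct from geometry errors.
#' @export
findThreshold <- function(empirical, null) {
  stopifnot(is(empirical, "CellSizePDF"))
  ctr <- binCenters(empirical@breaks)
  ref <- referenceDensity(null, empirical@breaks)
  dif <- empirical@density - ref
  # arm the scan only where the observed bin count exceeds an exact Poisson
  # tail bound under the null, so that pure noise on clusterless data does
  # not produce a threshold; the crossing rule itself is unaffected
  if (is.finite(empirical@nSamples)) {
    w <- diff(empirical@breaks)
    counts <- empirical@density * empirical@nSamples * w
    expected <- ref * empirical@nSamples * w
    above <- which(counts > stats::qpois(1 - 1e-8, expected) & dif > 0)
  } else {
    above <- which(dif > 0)
  }
  if (!length(above))
    vcStop("no small-cell excess over the null: nothing to segment",
           "no_cluster_signal")
  k0 <- above[1L]
  cross <- which(seq_along(dif) > k0 & dif <= 0)
  if (!length(cross))
    vcStop("experimental density never returns below the null",
           "no_cluster_signal")
  b <- cross[1L]
  a <- b - 1L
  yStar <- ctr[a] + dif[a] * (ctr[b] - ctr[a]) / (dif[a] - dif[b])
  meanS <- empirical@meanSize
  kind <- if (is(null, "MonteCarloNull")) "monte_carlo" else "analytical"
  new("VoronoiThreshold", yStar = yStar,
      sStar = if (is.finite(meanS)) yStar * meanS else NA_real_,
      meanSize = meanS, nullKind = kind)
}

setMethod("show", "VoronoiThreshold", function(object) {
  cat(sprintf("VoronoiThreshold (%s): y* = %.4g, s* = %.6g\n",
              object@nullKind, object@yStar, object@sStar))
})

#' Select cells below the threshold
#'
#' A cell is selected iff it is not a border cell and its size is strictly
#' below the absolute threshold `sStar`.
#'
#' @param vd A [VoronoiDiagram-class].
#' @param threshold A [VoronoiThreshold-class] derived from the same
#'   diagram's normalization (or a bare numeric absolute threshold).
#' @return Logical vector, one flag per cell.
#' @export
selectCells <- function(vd, threshold) {
  stopifnot(is(vd, "VoronoiDiagram"))
  sStar <- if (is(threshold, "VoronoiThreshold")) threshold@sStar
           else as.numeric(threshold)
  vcAssert(is.finite(sStar), "threshold has no absolute size", "input")
  !isBorder(vd) & cellSizes(vd) < sStar
}

#' Extract clusters as connected components of selected cells
#'
#' Builds the graph whose vertices are the selected cells and whose edges
#' are Delaunay one-ring adjacencies (equivalently Voronoi facet
#' adjacencies) between two selected cells, and returns its connected
#' components with at least `minLocs` members.  Member indices are
#' re-expanded to original localization rows (duplicates rejoin their
#' generator); cluster volume is the sum of member cell sizes and the
#' barycenter the unweighted mean of member coordinates.
#'
#' @param vd A [VoronoiDiagram-class].
#' @param selected Logical selection from [selectCells()].
#' @param minLocs Minimum localizations per cluster (default 5).
#' @param threshold Optional [VoronoiThreshold-class] recorded in the
#'   result.
#' @param parameters Optional provenance list.
#' @return A [ClusteringResult-class]; an empty selection yields zero
#'   clusters.
#' @export
extractClusters <- function(vd, selected, minLocs = 5L, threshold = NULL,
                            parameters = list()) {
  stopifnot(is(vd, "VoronoiDiagram"))
  dt <- vd@delaunay
  n <- length(vd@sizes)
  vcAssert(length(selected) == n, "selection must match the diagram", "input")
  idx <- which(selected)
  comp <- integer(0)
  if (length(idx)) {
    # edges of the selected-cell subgraph
    deg <- diff(dt@ringStart)[idx]
    from <- rep(idx, deg)
    to <- dt@ringIdx[sequence(nvec = deg, from = dt@ringStart[idx])]
    ok <- selected[to] & to > from
    g <- igraph::graph_from_edgelist(cbind(match(from[ok], idx),
                                           match(to[ok], idx)),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) -
                                       igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  mem <- split(idx, comp)
  mem <- mem[vapply(mem, length, 1L) >= 1L]
  if (is.null(threshold))
    threshold <- new("VoronoiThreshold", yStar = NA_real_, sStar = NA_real_,
                     meanSize = meanCellSize(vd), nullKind = "manual")
  co <- locCoords(dt@points)
  d <- ncol(co)
  rows <- split(seq_along(dt@dupMap), dt@dupMap)  # generator -> original rows
  clusters <- list()
  members <- list()
  for (m in mem) {
    orig <- unlist(rows[as.character(m)], use.names = FALSE)
    if (length(orig) < minLocs) next
    members[[length(members) + 1L]] <- sort(orig)
    bc <- colMeans(co[orig, , drop = FALSE])
    clusters[[length(clusters) + 1L]] <-
      c(nLocs = length(orig), volume = sum(vd@sizes[m]), bc)
  }
  if (length(clusters)) {
    df <- as.data.frame(do.call(rbind, clusters))
    names(df) <- c("nLocs", "volume", paste0("barycenter.",
                                             c("x", "y", "z")[seq_len(d)]))
    df <- cbind(id = seq_len(nrow(df)), df)
  } else {
    df <- data.frame(id = integer(), nLocs = integer(), volume = numeric())
  }
  new("ClusteringResult", threshold = threshold, selected = selected,
      clusters = df, members = members,
      parameters = c(parameters, list(minLocs = as.integer(minLocs))))
}

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult: %d clusters (%s null, y* = %.4g)\n",
              nrow(object@clusters), object@threshold@nullKind,
              object@threshold@yStar))
  if (nrow(object@clusters) > 0L)
    cat(sprintf("  localizations in clusters: %d; median volume: %.6g\n",
                sum(object@clusters$nLocs), median(object@clusters$volume)))
})

#' Number of clusters in a result
#' @param cr A [ClusteringResult-class].
#' @return Integer count.
#' @export
nClusters <- function(cr) nrow(cr@clusters)

#' Pair two clusterings and compare matched volumes
#'
#' Pairs every cluster of `a` with the cluster of `b` sharing the most
#' members (ties broken by nearest barycenter) and reports the paired
#' table together with the mean relative volume difference
#' \eqn{|V_a - V_b| / V_a \times 100} over the pairs.  Unpaired clusters
#' are listed separately.
#'
#' @param a,b [ClusteringResult-class] objects from the same localization
#'   set.
#' @return List with `pairs` (data.frame), `meanVolumeDiff` (percent),
#'   `unpairedA`, `unpairedB`.
#' @export
matchClusters <- function(a, b) {
  stopifnot(is(a, "ClusteringResult"), is(b, "ClusteringResult"))
  if (nClusters(a) == 0L || nClusters(b) == 0L) {
    warning("empty clustering: volume difference undefined")
    return(list(pairs = data.frame(), meanVolumeDiff = NA_real_,
                unpairedA = seq_len(nClusters(a)),
                unpairedB = seq_len(nClusters(b))))
  }
  bcA <- as.matrix(a@clusters[, grep("^barycenter", names(a@clusters)),
                              drop = FALSE])
  bcB <- as.matrix(b@clusters[, grep("^barycenter", names(b@clusters)),
                              drop = FALSE])
  pairs <- lapply(seq_len(nClusters(a)), function(i) {
    ov <- vapply(b@members, function(m)
      length(intersect(m, a@members[[i]])), 1L)
    best <- max(ov)
    if (best == 0L) return(NULL)
    j <- which(ov == best)
    if (length(j) > 1L) {
      dd <- rowSums((bcB[j, , drop = FALSE] -
                       matrix(bcA[i, ], length(j), ncol(bcA),
                              byrow = TRUE))^2)
      j <- j[which.min(dd)]
    }
    va <- a@clusters$volume[i]
    vb <- b@clusters$volume[j]
    data.frame(a = i, b = j, overlap = best, volumeA = va, volumeB = vb,
               relDiff = abs(va - vb) / va * 100)
  })
  pairs <- do.call(rbind, pairs)
  list(pairs = pairs,
       meanVolumeDiff = if (is.null(pairs)) NA_real_ else mean(pairs$relDiff),
       unpairedA = setdiff(seq_len(nClusters(a)), pairs$a),
       unpairedB = setdiff(seq_len(nClusters(b)), pairs$b))
}

#' SR-Tesseler-style density-factor segmentation
#'
#' Selects cells whose local density (the inverse cell size) is at least
#' `alpha` times the average density, i.e. cells with
#' \eqn{S < \langle S\rangle / \alpha}, then extracts connected clusters.
#' This is the minimal single-level form of density-based tessellation
#' segmentation, provided for comparison with the statistical threshold.
#'
#' @param vd A [VoronoiDiagram-class].
#' @param alpha Positive density factor (1 selects cells denser than
#'   average).
#' @param minLocs Minimum localizations per cluster.
#' @return A [ClusteringResult-class].
#' @export
segmentByDensityFactor <- function(vd, alpha, minLocs = 5L) {
  vcAssert(is.numeric(alpha) && length(alpha) == 1L && alpha > 0,
           "alpha must be a positive scalar", "input")
  meanS <- meanCellSize(vd)
  thr <- new("VoronoiThreshold", yStar = 1 / alpha, sStar = meanS / alpha,
             meanSize = meanS, nullKind = "density_factor")
  extractClusters(vd, selectCells(vd, thr), minLocs = minLocs,
                  threshold = thr,
                  parameters = list(alpha = alpha))
}

#' ClusterVisu: statistical Voronoi cluster segmentation
#'
#' The full pipeline: tessellate (if needed), estimate the null cell-size
#' distribution (Monte-Carlo simulations of uniform points, or the
#' closed-form gamma approximation), find the threshold as the distribution
#' intersection, select sub-threshold cells and extract connected clusters.
#'
#' @param x A [LocalizationSet-class] or a prebuilt [VoronoiDiagram-class].
#' @param null `"monte_carlo"` or `"analytical"`.
#' @param nSims Number of Monte-Carlo simulations (default 50).
#' @param seed Seed for the Monte-Carlo null.
#' @param breaks Histogram bin edges; default [defaultBreaks()].
#' @param minLocs Minimum localizations per cluster (default 5).
#' @param clipBounds Passed to [buildVoronoi()] when `x` is a localization
#'   set.
#' @return A [ClusteringResult-class].
#' @export
#' @examples
#' cfg <- clusterSimConfig(nClusters = 4, locsPerCluster = 120,
#'                         bounds = boundingBox(c(0, 0), c(2000, 2000)),
#'                         sigma = 40, dim = 2, seed = 7)
#' locs <- simulateClustered(cfg)
#' cr <- clusterVisu(locs, null = "analytical")
#' nClusters(cr)
clusterVisu <- function(x, null = c("monte_carlo", "analytical"),
                        nSims = 50L, seed = 1L, breaks = defaultBreaks(),
                        minLocs = 5L, clipBounds = "auto") {
  null <- match.arg(null)
  vd <- if (is(x, "VoronoiDiagram")) x else buildVoronoi(x, clipBounds)
  emp <- cellSizePDF(vd, breaks = breaks)
  nullModel <- if (null == "analytical") {
    analyticalNull(ncol(vd@dataBounds))
  } else {
    monteCarloNull(length(vd@sizes), vd@dataBounds, nSims = nSims,
                   seed = seed, breaks = breaks)
  }
  thr <- findThreshold(emp, nullModel)
  sel <- selectCells(vd, thr)
  extractClusters(vd, sel, minLocs = minLocs, threshold = thr,
                  parameters = list(null = null, nSims = if (null ==
                    "monte_carlo") as.integer(nSims) else NA_integer_,
                    seed = as.integer(seed),
                    breaks = range(breaks), nBins = length(breaks) - 1L))
}

#' Export a cluster table as CSV
#'
#' @param cr A [ClusteringResult-class].
#' @param path Output path.
#' @param labels If TRUE, also return the per-localization cluster label
#'   vector (0 = unclustered).
#' @return Invisibly, the label vector (if requested) or `path`.
#' @export
exportClusters <- function(cr, path, labels = FALSE) {
  write.csv(cr@clusters, path, row.names = FALSE)
  if (labels) {
    n <- max(unlist(cr@members, use.names = FALSE), 0L)
    lab <- integer(n)
    for (i in seq_along(cr@members)) lab[cr@members[[i]]] <- i
    return(invisible(lab))
  }
  invisible(path)
}
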