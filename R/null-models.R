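#' Normalize cell sizes by the mean over non-border cells
#'
#' Computes \eqn{y_i = S_i / \langle S \rangle} where the mean
#' \eqn{\langle S \rangle} is taken over non-border cells only; border
#' cells are excluded from the output as well, so the result always has
#' mean one.
#'
#' @param sizes Numeric cell sizes (nm^2 or nm^3), or a
#'   [VoronoiDiagram-class] (in which case `borderMask` defaults to its
#'   border flags).
#' @param borderMask Logical border flags, same length as `sizes`.
#' @return Numeric vector of dimensionless normalized sizes, with the
#'   normalizing mean attached as attribute `"meanSize"`.
#' @export
#' @examples
#' normalizeSizes(c(2, 4, 6), c(FALSE, FALSE, TRUE))
normalizeSizes <- function(sizes, borderMask = NULL) {
  if (is(sizes, "VoronoiDiagram")) {
    if (is.null(borderMask)) borderMask <- isBorder(sizes)
    sizes <- cellSizes(sizes)
  }
  if (is.null(borderMask)) borderMask <- rep(FALSE, length(sizes))
  vcAssert(length(borderMask) == length(sizes),
           "border mask must match sizes", "input")
  keep <- sizes[!borderMask]
  vcAssert(length(keep) > 0L, "all cells are border cells", "empty_sample")
  structure(keep / mean(keep), meanSize = mean(keep))
}

#' Closed-form Poisson-Voronoi cell-size densities
#'
#' The fixed gamma approximations of the normalized cell-size distribution
#' of a Voronoi tessellation of uniformly random points:
#' \deqn{f_{2D}(y) = \frac{343}{15}\sqrt{\frac{7}{2\pi}}\, y^{5/2}
#'   e^{-7y/2}, \qquad
#'   f_{3D}(y) = \frac{3125}{24}\, y^{4} e^{-5y}.}
#' Both are gamma densities (shape 7/2, rate 7/2 in 2D; shape 5, rate 5 in
#' 3D): they integrate to one and have unit mean, matching the
#' normalization \eqn{y = S/\langle S\rangle}.
#'
#' @param y Nonnegative normalized cell sizes.
#' @param dim 2 or 3.
#' @return Density values at `y`.
#' @export
#' @examples
#' analyticalPDF(0.8, 3)      # near the 3D mode at y = 4/5
#' integrate(analyticalPDF, 0, Inf, dim = 3)
analyticalPDF <- function(y, dim) {
  vcAssert(all(dim %in% 2:3), "dim must be 2 or 3", "input")
  vcAssert(all(y >= 0), "normalized sizes must be nonnegative", "domain")
  if (dim == 3L) 3125 / 24 * y^4 * exp(-5 * y)
  else 343 / 15 * sqrt(7 / (2 * pi)) * y^(5 / 2) * exp(-7 * y / 2)
}

#' Analytical (gamma) null model
#'
#' @param dim 2 or 3.
#' @return An [AnalyticalNull-class].
#' @export
#' @examples
#' nullDensity(analyticalNull(3), c(0.5, 1, 2))
analyticalNull <- function(dim) {
  vcAssert(length(dim) == 1L && dim %in% 2:3, "dim must be 2 or 3", "input")
  s <- if (dim == 3) 5 else 3.5
  new("AnalyticalNull", dim = as.integer(dim), shape = s, rate = s)
}

#' @rdname nullDensity
#' @export
setMethod("nullDensity", "AnalyticalNull",
          function(object, y) analyticalPDF(y, object@dim))

setMethod("show", "AnalyticalNull", function(object) {
  cat(sprintf(
    "AnalyticalNull: %dD Poisson-Voronoi gamma (shape %.3g, rate %.3g)\n",
    object@dim, object@shape, object@rate))
})

#' Density-normalized histogram of normalized cell sizes
#'
#' Bins a sample of normalized sizes on fixed edges; values above the last
#' edge are dropped and their mass is reported in the result, so that
#' `sum(density * binwidth) + droppedMass == 1`.
#'
#' @param y Numeric sample (e.g. from [normalizeSizes()]).
#' @param breaks Increasing bin edges; default [defaultBreaks()].
#' @param meanSize Optional normalizing mean cell size to record (taken
#'   from the `"meanSize"` attribute of `y` when present).
#' @return A [CellSizePDF-class].
#' @export
#' @examples
#' empiricalPDF(rep(1, 100), breaks = seq(0, 2, by = 0.1))
empiricalPDF <- function(y, breaks = defaultBreaks(), meanSize = NULL) {
  vcAssert(length(y) > 0L, "empty sample", "empty_sample")
  vcAssert(length(breaks) >= 2L && !is.unsorted(breaks, strictly = TRUE),
           "breaks must be strictly increasing", "input")
  if (is.null(meanSize))
    meanSize <- attr(y, "meanSize") %||% NA_real_
  n <- length(y)
  inside <- y >= breaks[1L] & y <= breaks[length(breaks)]
  cnt <- hist(y[inside], breaks = breaks, plot = FALSE)$counts
  dens <- cnt / (n * diff(breaks))
  new("CellSizePDF", breaks = breaks, density = dens, nSamples = as.integer(n),
      meanSize = as.numeric(meanSize),
      droppedMass = 1 - sum(inside) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell-size distribution of a Voronoi diagram
#'
#' Convenience wrapper: normalize the non-border cell sizes and bin them.
#'
#' @param vd A [VoronoiDiagram-class].
#' @param breaks Bin edges; default [defaultBreaks()].
#' @return A [CellSizePDF-class] carrying the normalizing mean size.
#' @export
cellSizePDF <- function(vd, breaks = defaultBreaks()) {
  stopifnot(is(vd, "VoronoiDiagram"))
  empiricalPDF(normalizeSizes(vd), breaks = breaks)
}

setMethod("show", "CellSizePDF", function(object) {
  cat(sprintf(
    "CellSizePDF: %d bins on [%g, %g], n = %d, dropped mass %.2g\n",
    length(object@density), min(object@breaks), max(object@breaks),
    object@nSamples, object@droppedMass))
})

#' Monte-Carlo null model for cell-size distributions
#'
#' Simulates `nSims` uniform (complete spatial randomness) point clouds
#' with the same number of localizations and the same bounding volume as
#' the data, tessellates each, removes border cells, normalizes sizes by
#' their mean and bins them on shared edges.  Returns the per-simulation
#' densities, their bin-wise mean, and a pointwise envelope (min/max by
#' default, or the requested quantiles).  Per-simulation seeds are derived
#' deterministically from `seed`, so the result is reproducible
#' bit for bit.
#'
#' @param nPoints Number of points per simulation.
#' @param bounds Bounding volume to fill (a [boundingBox()]).
#' @param nSims Number of simulations (default 50).
#' @param seed Master seed.
#' @param breaks Bin edges; default [defaultBreaks()].
#' @param envelopeQuantiles Optional length-2 probabilities for a quantile
#'   envelope instead of min/max.
#' @return A [MonteCarloNull-class].
#' @export
#' @examples
#' mc <- monteCarloNull(500, boundingBox(c(0, 0), c(1000, 1000)),
#'                      nSims = 3, seed = 1)
#' mc
monteCarloNull <- function(nPoints, bounds, nSims = 50L, seed = 1L,
                           breaks = defaultBreaks(),
                           envelopeQuantiles = NULL) {
  vcAssert(nSims >= 1L, "need at least one simulation", "input")
  d <- ncol(bounds)
  vcAssert(nPoints >= d + 1L, "too few points to triangulate", "input")
  set.seed(seed)
  simSeeds <- sample.int(.Machine$integer.max - 1L, nSims)
  nb <- length(breaks) - 1L
  perSim <- matrix(NA_real_, nb, nSims)
  for (s in seq_len(nSims)) {
    locs <- simulateUniform(nPoints, bounds, simSeeds[s])
    vd <- tryCatch(buildVoronoi(locs, clipBounds = "auto"),
                   error = function(e)
                     vcStop(sprintf("simulation %d failed: %s", s,
                                    conditionMessage(e)), "geometry"))
    perSim[, s] <- empiricalPDF(normalizeSizes(vd), breaks = breaks)@density
  }
  if (is.null(envelopeQuantiles)) {
    lower <- apply(perSim, 1L, min)
    upper <- apply(perSim, 1L, max)
    envelopeQuantiles <- numeric()
  } else {
    vcAssert(length(envelopeQuantiles) == 2L, "need two quantiles", "input")
    qs <- apply(perSim, 1L, stats::quantile, probs = envelopeQuantiles)
    lower <- qs[1L, ]
    upper <- qs[2L, ]
  }
  new("MonteCarloNull", breaks = breaks, perSim = perSim,
      meanDensity = rowMeans(perSim), lower = lower, upper = upper,
      nSims = as.integer(nSims), seed = as.integer(seed),
      nPoints = as.integer(nPoints), bounds = bounds,
      envelopeQuantiles = as.numeric(envelopeQuantiles))
}

#' @rdname nullDensity
#' @export
setMethod("nullDensity", "MonteCarloNull", function(object, y) {
  # piecewise-constant interpolation of the bin-wise mean density
  idx <- findInterval(y, object@breaks, rightmost.closed = TRUE)
  out <- rep(0, length(y))
  ok <- idx >= 1L & idx <= length(object@meanDensity)
  out[ok] <- object@meanDensity[idx[ok]]
  out
})

setMethod("show", "MonteCarloNull", function(object) {
  cat(sprintf(
    "MonteCarloNull: %d simulations of %d points (seed %d), %d bins\n",
    object@nSims, object@nPoints, object@seed, nrow(object@perSim)))
})

#' Per-simulation distribution of a Monte-Carlo null
#' @param mc A [MonteCarloNull-class].
#' @param i Simulation index.
#' @return The i-th simulation's [CellSizePDF-class].
#' @export
perSimPDF <- function(mc, i) {
  stopifnot(is(mc, "MonteCarloNull"))
  vcAssert(i >= 1L && i <= mc@nSims, "simulation index out of range", "index")
  dens <- mc@perSim[, i]
  new("CellSizePDF", breaks = mc@breaks, density = dens,
      nSamples = NA_integer_, meanSize = NA_real_,
      droppedMass = 1 - sum(dens * diff(mc@breaks)))
}

#' Deviation between an empirical distribution and a reference
#'
#' Mean (or maximum) absolute difference between the empirical density and
#' the reference density evaluated at bin centers, expressed as a
#' percentage of the reference's peak density.
#'
#' @param empirical A [CellSizePDF-class].
#' @param reference An [AnalyticalNull-class], [MonteCarloNull-class], or
#'   [CellSizePDF-class] on the same bins.
#' @param metric `"mean_abs"` (default) or `"max_abs"`.
#' @return Percentage deviation (scalar).
#' @export
pdfDeviation <- function(empirical, reference,
                         metric = c("mean_abs", "max_abs")) {
  metric <- match.arg(metric)
  stopifnot(is(empirical, "CellSizePDF"))
  vcAssert(length(empirical@breaks) >= 2L, "empty bins", "input")
  ctr <- binCenters(empirical@breaks)
  ref <- referenceDensity(reference, empirical@breaks)
  dev <- abs(empirical@density - ref)
  100 * (if (metric == "mean_abs") mean(dev) else max(dev)) / max(ref)
}

referenceDensity <- function(reference, breaks) {
  ctr <- binCenters(breaks)
  if (is(reference, "AnalyticalNull")) return(nullDensity(reference, ctr))
  if (is(reference, "MonteCarloNull")) {
    vcAssert(isTRUE(all.equal(reference@breaks, breaks)),
             "reference must share the empirical bins", "input")
    return(reference@meanDensity)
  }
  if (is(reference, "CellSizePDF")) {
    vcAssert(isTRUE(all.equal(reference@breaks, breaks)),
             "reference must share the empirical bins", "input")
    return(reference@density)
  }
  vcStop("unsupported reference type", "input")
}

#' Two-sample location / distribution tests
#'
#' Thin wrapper over the standard two-sample Wilcoxon rank-sum and
#' Kolmogorov-Smirnov tests.
#'
#' @param a,b Numeric samples (length >= 2).
#' @param test `"wilcoxon_rank"` or `"ks"`.
#' @return List with `statistic`, `p.value` and `test`.
#' @export
#' @examples
#' compareSamples(rnorm(50), rnorm(50), "ks")
compareSamples <- function(a, b, test = c("wilcoxon_rank", "ks")) {
  test <- match.arg(test)
  vcAssert(length(a) >= 2L && length(b) >= 2L,
           "samples must have at least 2 values", "input")
  r <- if (test == "wilcoxon_rank") suppressWarnings(wilcox.test(a, b))
       else suppressWarnings(ks.test(a, b))
  list(statistic = unname(r$statistic), p.value = unname(r$p.value),
       test = test)
}

#' Plot a cell-size distribution against a null model
#'
#' @param x A [CellSizePDF-class].
#' @param null Optional null model ([AnalyticalNull-class] or
#'   [MonteCarloNull-class]) overlaid for comparison.
#' @param ... Passed to [plot()].
#' @export
plotPDF <- function(x, null = NULL, ...) {
  ctr <- binCenters(x@breaks)
  plot(ctr, x@density, type = "s", xlab = "normalized cell size y",
       ylab = "density", ...)
  if (!is.null(null)) {
    if (is(null, "MonteCarloNull")) {
      polygon(c(ctr, rev(ctr)), c(null@lower, rev(null@upper)),
              col = grDevices::adjustcolor("orange", 0.3), border = NA)
      lines(ctr, null@meanDensity, col = "blue")
    } else {
      lines(ctr, nullDensity(null, ctr), col = "darkgoldenrod")
    }
  }
  invisible(NULL)
}

#' Export a distribution or null model as CSV
#'
#' Two columns (`bin_center`, `density`) for a [CellSizePDF-class]; four
#' (`bin_center`, `mean`, `lower`, `upper`) for a [MonteCarloNull-class].
#'
#' @param x The object to export.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
exportPDF <- function(x, path) {
  if (is(x, "CellSizePDF")) {
    df <- data.frame(bin_center = binCenters(x@breaks), density = x@density)
  } else if (is(x, "MonteCarloNull")) {
    df <- data.frame(bin_center = binCenters(x@breaks), mean = x@meanDensity,
                     lower = x@lower, upper = x@upper)
  } else vcStop("unsupported object for exportPDF", "input")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
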