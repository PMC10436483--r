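# shared fixtures and independent oracles

# uniform random localization set in a cube
randomLocs <- function(n, dim = 3, side = 100, seed = 1) {
  set.seed(seed)
  LocalizationSet(matrix(runif(dim * n) * side, ncol = dim))
}

# regular grid of points with unit spacing
gridLocs <- function(k, dim = 3) {
  g <- as.matrix(do.call(expand.grid, rep(list(0:(k - 1)), dim)))
  storage.mode(g) <- "double"
  colnames(g) <- c("x", "y", "z")[seq_len(dim)]
  LocalizationSet(g)
}

# all-pairs brute-force cell size: clip the cell of point i against every
# other point, not just the one-ring
allPairsCell <- function(locs, i, clipBounds = "auto") {
  constructCell(locs, i, neighbors = NULL, clipBounds = clipBounds)
}

# brute-force empty-circumsphere check: for every simplex, no input point
# lies strictly inside its circumsphere (relative tolerance)
circumsphereViolations <- function(coords, simp, tol = 1e-9) {
  d <- ncol(coords)
  bad <- 0L
  for (s in seq_len(nrow(simp))) {
    v <- coords[simp[s, ], , drop = FALSE]
    A <- 2 * sweep(v[-1L, , drop = FALSE], 2L, v[1L, ])
    rhs <- rowSums(v[-1L, , drop = FALSE]^2) - sum(v[1L, ]^2)
    ctr <- tryCatch(solve(A, rhs), error = function(e) rep(NA_real_, d))
    if (anyNA(ctr)) next
    r2 <- sum((v[1L, ] - ctr)^2)
    d2 <- rowSums(sweep(coords, 2L, ctr)^2)
    d2[simp[s, ]] <- Inf
    if (min(d2) < r2 * (1 - tol)) bad <- bad + 1L
  }
  bad
}

# polygon / polyhedron measure recomputed from explicit polytope geometry
polytopeMeasure <- function(poly) {
  v <- poly$vertices
  if (ncol(v) == 2L) {
    # vertices form the CCW polygon loop
    n <- nrow(v)
    j <- c(2:n, 1L)
    return(abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2)
  }
  ctr <- colMeans(v)
  vol <- 0
  for (loop in poly$faces) {
    a <- v[loop[1L], ] - ctr
    for (t in seq_len(length(loop) - 2L)) {
      b <- v[loop[t + 1L], ] - ctr
      cc <- v[loop[t + 2L], ] - ctr
      vol <- vol + a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
        a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
        a[3] * (b[1] * cc[2] - b[2] * cc[1])
    }
  }
  abs(vol) / 6
}

# hand-built diagram for arithmetic-level tests of selection / extraction:
# sizes, border flags and an adjacency list are prescribed, not computed
fakeDiagram <- function(sizes, border, adj, coords = NULL) {
  n <- length(sizes)
  if (is.null(coords))
    coords <- cbind(seq_len(n), 0, 0)
  deg <- lengths(adj)
  locs <- LocalizationSet(coords)
  dt <- new("DelaunayComplex", points = locs, keep = seq_len(n),
            dupMap = seq_len(n), simplices = matrix(integer(), 0L, 4L),
            ringStart = as.integer(cumsum(c(1L, deg))),
            ringIdx = as.integer(unlist(adj)), joggled = FALSE)
  new("VoronoiDiagram", delaunay = dt, sizes = as.numeric(sizes),
      border = as.logical(border), nFacets = as.integer(deg),
      clipBounds = tightBox(coords), dataBounds = tightBox(coords))
}

# CellSizePDF with prescribed density (validity-checked)
pdfFrom <- function(breaks, density, meanSize = 1) {
  new("CellSizePDF", breaks = breaks, density = density,
      nSamples = NA_integer_, meanSize = meanSize,
      droppedMass = 1 - sum(density * diff(breaks)))
}
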