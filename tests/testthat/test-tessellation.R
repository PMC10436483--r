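test_that("a single tetrahedron triangulates to itself", {
  locs <- LocalizationSet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                c(0, 0, 1)))
  dt <- buildDelaunay(locs)
  expect_equal(nrow(simplices(dt)), 1L)
  expect_setequal(as.integer(simplices(dt)), 1:4)
  for (i in 1:4) expect_setequal(directNeighbors(dt, i), setdiff(1:4, i))
})

test_that("the centroid of a tetrahedron neighbours all four corners", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              c(0.25, 0.25, 0.25))
  dt <- buildDelaunay(LocalizationSet(co))
  expect_setequal(directNeighbors(dt, 5), 1:4)
  expect_equal(circumsphereViolations(co, simplices(dt)), 0L)
})

test_that("random triangulations satisfy the empty-circumsphere property", {
  locs <- randomLocs(1000, dim = 3, seed = 31)
  dt <- buildDelaunay(locs)
  expect_equal(circumsphereViolations(locCoords(locs), simplices(dt)), 0L)
  locs2 <- randomLocs(500, dim = 2, seed = 32)
  dt2 <- buildDelaunay(locs2)
  expect_equal(circumsphereViolations(locCoords(locs2), simplices(dt2)), 0L)
})

test_that("one-ring adjacency is symmetric and excludes the point itself", {
  dt <- buildDelaunay(randomLocs(300, seed = 33))
  ring <- oneRing(dt)
  for (i in seq_along(ring)) {
    expect_false(i %in% ring[[i]])
    for (j in ring[[i]]) expect_true(i %in% ring[[j]])
  }
  expect_error(directNeighbors(dt, 0), class = "vc_index_error")
  expect_error(directNeighbors(dt, 301), class = "vc_index_error")
})

test_that("the grid center point neighbours its six face-adjacent points", {
  locs <- gridLocs(3, dim = 3)
  dt <- buildDelaunay(locs)
  g <- locCoords(locs)
  center <- which(g[, 1] == 1 & g[, 2] == 1 & g[, 3] == 1)
  faceNb <- which(rowSums(abs(sweep(g, 2L, c(1, 1, 1)))) == 1)
  expect_true(all(faceNb %in% directNeighbors(dt, center)))
})

test_that("degenerate inputs raise geometry or input errors", {
  flat <- cbind(runif(10), runif(10), 0.5)
  expect_error(buildDelaunay(LocalizationSet(flat)),
               class = "vc_geometry_error")
  line2 <- cbind(1:10, 2 * (1:10))
  expect_error(buildDelaunay(LocalizationSet(line2)),
               class = "vc_geometry_error")
  expect_error(buildDelaunay(LocalizationSet(rbind(c(0, 0, 0), c(1, 1, 1)))),
               class = "vc_input_error")
})

test_that("exact duplicates are merged with a recorded mapping", {
  set.seed(34)
  co <- matrix(runif(30), ncol = 3)
  dup <- rbind(co, co[c(3, 7), ])
  dt <- buildDelaunay(LocalizationSet(dup))
  expect_equal(length(dt@keep), 10L)
  expect_equal(dt@dupMap[11:12], c(3L, 7L))
  vd <- buildVoronoi(dt)
  expect_equal(length(cellSizes(vd)), 10L)
})

test_that("a lone bisector halves the clip box", {
  locs <- LocalizationSet(rbind(c(0, 0, 0), c(2, 0, 0)),
                          bounds = boundingBox(c(-1, -1, -1), c(3, 1, 1)))
  cell <- constructCell(locs, 1, neighbors = 2, clipBounds = locBounds(locs))
  expect_equal(cell@size, 8)
  expect_true(cell@isBorder)
  expect_equal(cell@neighbors, 2L)
  # both mirror cells together fill the box
  vd <- buildVoronoi(locs, clipBounds = locBounds(locs))
  expect_equal(cellSizes(vd), c(8, 8))
})

test_that("an interior grid cell is the unit cube", {
  locs <- gridLocs(3, dim = 3)
  g <- locCoords(locs)
  center <- which(g[, 1] == 1 & g[, 2] == 1 & g[, 3] == 1)
  vd <- buildVoronoi(locs, clipBounds = expandBox(locBounds(locs), 1))
  expect_equal(cellSizes(vd)[center], 1, tolerance = 1e-12)
  expect_false(isBorder(vd)[center])
  poly <- cellPolytope(vd, center)
  expect_equal(nrow(poly$vertices), 8L)
  expect_equal(length(poly$faces), 6L)
  expect_equal(poly$size, 1, tolerance = 1e-12)
})

test_that("one-ring construction equals the all-pairs oracle", {
  for (dim in c(2L, 3L)) {
    locs <- randomLocs(200, dim = dim, seed = 35 + dim)
    vd <- buildVoronoi(locs)
    for (i in seq_len(nLocs(locs))) {
      oracle <- allPairsCell(locs, i)
      expect_lt(abs(oracle@size - cellSizes(vd)[i]) / oracle@size, 1e-9)
      expect_equal(oracle@isBorder, isBorder(vd)[i])
    }
  }
})

test_that("clipped cells partition the bounding volume", {
  for (dim in c(2L, 3L)) {
    locs <- randomLocs(1000, dim = dim, seed = 38 + dim)
    vd <- buildVoronoi(locs, clipBounds = locBounds(locs))
    expect_lt(abs(sum(cellSizes(vd)) - boxMeasure(locBounds(locs))) /
                boxMeasure(locBounds(locs)), 1e-6)
  }
})

test_that("cell sizes are invariant under translation and rotation", {
  locs <- randomLocs(150, dim = 3, seed = 41)
  vd <- buildVoronoi(locs)
  co <- locCoords(locs)
  # translation
  vdT <- buildVoronoi(LocalizationSet(sweep(co, 2L, c(1234.5, -77.1, 3.2),
                                            "+")))
  expect_equal(cellSizes(vdT), cellSizes(vd), tolerance = 1e-6)
  # rotation about z then x
  th <- 0.7; ph <- 1.1
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  # rotation reorients the axis-aligned bounding box, so only cells that
  # are interior under both clippings are geometrically unchanged
  vdR <- buildVoronoi(LocalizationSet(co %*% t(Rx %*% Rz)))
  keep <- !isBorder(vdR) & !isBorder(vd)
  expect_gt(sum(keep), 20)
  expect_equal(cellSizes(vdR)[keep], cellSizes(vd)[keep], tolerance = 1e-6)
})

test_that("results are deterministic and independent of row order", {
  locs <- randomLocs(400, dim = 3, seed = 42)
  vd1 <- buildVoronoi(locs)
  vd2 <- buildVoronoi(locs)
  expect_identical(cellSizes(vd1), cellSizes(vd2))
  set.seed(43)
  perm <- sample(nLocs(locs))
  vdP <- buildVoronoi(LocalizationSet(locCoords(locs)[perm, ]))
  expect_equal(cellSizes(vdP), cellSizes(vd1)[perm], tolerance = 1e-12)
  expect_identical(isBorder(vdP), isBorder(vd1)[perm])
})

test_that("explicit polytope measure matches the cell size", {
  locs <- randomLocs(120, dim = 3, seed = 44)
  vd <- buildVoronoi(locs)
  for (i in seq(1, 120, by = 7)) {
    poly <- cellPolytope(vd, i)
    expect_lt(abs(polytopeMeasure(poly) - cellSizes(vd)[i]) /
                cellSizes(vd)[i], 1e-9)
  }
})

test_that("border flags agree with a vertex-containment oracle", {
  locs <- randomLocs(250, dim = 3, seed = 45)
  vd <- buildVoronoi(locs)  # auto clip: expanded box, flags vs data bounds
  b <- locBounds(locs)
  tol <- 1e-9 * sqrt(sum((b[2, ] - b[1, ])^2))
  for (i in seq_len(250)) {
    v <- cellPolytope(vd, i)$vertices
    outside <- any(t(v) < b[1, ] - tol) || any(t(v) > b[2, ] + tol)
    expect_equal(isBorder(vd)[i], outside)
  }
})

test_that("re-flagging against a smaller volume removes edge cells", {
  locs <- gridLocs(4, dim = 3)
  vd <- buildVoronoi(locs, clipBounds = expandBox(locBounds(locs), 1))
  g <- locCoords(locs)
  hull <- apply(g == 0 | g == 3, 1L, any)
  expect_true(all(isBorder(vd)[hull]))
  expect_false(any(isBorder(vd)[!hull]))
  # shrink the reference volume: now every cell crosses it
  inner <- boundingBox(rep(1.2, 3), rep(1.8, 3))
  vd2 <- flagBorderCells(vd, inner)
  expect_true(all(isBorder(vd2)))
})

test_that("2D cell areas agree with an independent tessellation library", {
  skip_if_not_installed("deldir")
  locs <- randomLocs(300, dim = 2, seed = 46)
  co <- locCoords(locs)
  b <- locBounds(locs)
  vd <- buildVoronoi(locs, clipBounds = b)
  dd <- deldir::deldir(co[, 1], co[, 2],
                       rw = c(b[1, 1], b[2, 1], b[1, 2], b[2, 2]))
  expect_equal(cellSizes(vd), dd$summary$dir.area, tolerance = 1e-6)
})

test_that("3D cell volumes match a frozen Qhull half-space oracle", {
  # expected volumes computed once with an independent half-space
  # intersection code (scipy/Qhull) for this exact deterministic fixture
  set.seed(424242)
  co <- matrix(runif(3 * 40) * 100, ncol = 3)
  locs <- LocalizationSet(co, bounds = boundingBox(rep(-10, 3), rep(110, 3)))
  vd <- buildVoronoi(locs, clipBounds = locBounds(locs))
  expected <- c(
    32930.33131711012, 65107.12642372621, 15108.06426625677,
    42028.35494084262, 45585.41950065009, 69874.8175629078,
    10899.937666122873, 60651.28140975669, 21278.90415956678,
    39667.294337902305, 58301.82364977684, 31586.426553152894,
    63633.500520524605, 28685.554681628382, 48093.994593454285,
    7696.438037946944, 5299.128871432371, 94461.12721445959,
    134555.4582594991, 57209.36894979758, 79689.66467572271,
    86015.13609106975, 26174.5037096309, 23832.770757580638,
    57092.38249923204, 29213.98685763873, 31053.57848169228,
    38178.075440519184, 52048.22021552724, 61527.233645642336,
    13560.693593418517, 51993.84491090036, 37393.04258733137,
    24590.714908710146, 60947.315865314886, 24092.778611214144,
    25871.08083737328, 19350.34523974447, 18081.6544496082,
    34638.62370561393)
  expect_equal(cellSizes(vd), expected, tolerance = 1e-9)
})

test_that("OFF export writes a readable polyhedron", {
  locs <- gridLocs(3, dim = 3)
  vd <- buildVoronoi(locs, clipBounds = expandBox(locBounds(locs), 1))
  f <- withr::local_tempfile(fileext = ".off")
  writeOFF(cellPolytope(vd, 14), f)
  lines <- readLines(f)
  expect_equal(lines[1], "OFF")
  expect_equal(strsplit(lines[2], " ")[[1]][1:2], c("8", "6"))
})
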