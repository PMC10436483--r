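test_that("the threshold is the first above-to-below crossing", {
  # experimental: 1.7 on [0, 0.5), 0.1 on [0.5, 2); null: constant 0.5
  br <- seq(0, 2, by = 0.1)
  emp <- pdfFrom(br, c(rep(1.7, 5), rep(0.1, 15)))
  ref <- pdfFrom(br, rep(0.5, 20))
  thr <- findThreshold(emp, ref)
  # crossing of the interpolants between centers 0.45 and 0.55:
  # diff goes +1.2 -> -0.4, root at 0.45 + 1.2 * 0.1 / 1.6
  expect_equal(thr@yStar, 0.45 + 1.2 * 0.1 / 1.6, tolerance = 1e-12)
  expect_equal(thr@sStar, thr@yStar)  # meanSize = 1
  # identical distributions carry no cluster signal
  expect_error(findThreshold(ref, ref), class = "vc_no_cluster_signal_error")
})

test_that("thresholds against both null kinds label their origin", {
  br <- seq(0, 2, by = 0.1)
  emp <- pdfFrom(br, c(rep(1.7, 5), rep(0.1, 15)), meanSize = 200)
  thrA <- findThreshold(emp, analyticalNull(3))
  expect_identical(thrA@nullKind, "analytical")
  expect_equal(thrA@sStar, thrA@yStar * 200)
})

test_that("cell selection applies the absolute threshold to non-border cells", {
  vd <- fakeDiagram(sizes = c(1, 2, 3, 4), border = rep(FALSE, 4),
                    adj = list(2L, c(1L, 3L), c(2L, 4L), 3L))
  # <S> = 2.5; y* = 1 selects sizes below 2.5
  thr <- new("VoronoiThreshold", yStar = 1, sStar = 2.5, meanSize = 2.5,
             nullKind = "manual")
  expect_equal(selectCells(vd, thr), c(TRUE, TRUE, FALSE, FALSE))
  # a vanishing threshold selects nothing; a huge one all non-border cells
  expect_equal(sum(selectCells(vd, 1e-12)), 0L)
  vd2 <- fakeDiagram(sizes = c(1, 2, 3, 4), border = c(FALSE, TRUE, FALSE,
                                                       FALSE),
                     adj = list(2L, c(1L, 3L), c(2L, 4L), 3L))
  expect_equal(selectCells(vd2, 1e9), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("clusters are connected components of selected cells", {
  # chain 1-2-3, gap, chain 5-6; cell 4 unselected
  adj <- list(2L, c(1L, 3L), c(2L, 4L), c(3L, 5L), c(4L, 6L), 5L)
  vd <- fakeDiagram(sizes = rep(1, 6), border = rep(FALSE, 6), adj = adj)
  sel <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  cr <- extractClusters(vd, sel, minLocs = 1L)
  expect_equal(nClusters(cr), 2L)
  expect_equal(sort(vapply(cr@members, length, 1L)), c(2L, 3L))
  expect_equal(sum(cr@clusters$nLocs), 5L)
  # volumes are sums of member cell sizes
  expect_equal(sort(cr@clusters$volume), c(2, 3))
  # minLocs filters small components; an empty selection yields none
  expect_equal(nClusters(extractClusters(vd, sel, minLocs = 3L)), 1L)
  expect_equal(nClusters(extractClusters(vd, sel, minLocs = 10L)), 0L)
  expect_equal(nClusters(extractClusters(vd, rep(FALSE, 6))), 0L)
  # fully selected connected set: a single cluster
  cr1 <- extractClusters(vd, rep(TRUE, 6), minLocs = 1L)
  expect_equal(nClusters(cr1), 1L)
  expect_equal(cr1@clusters$nLocs, 6L)
})

test_that("duplicate localizations rejoin their generator's cluster", {
  co <- cbind(c(1, 2, 3, 10, 11, 2), 0, 0)  # row 6 duplicates row 2
  vd <- fakeDiagram(sizes = rep(1, 5), border = rep(FALSE, 5),
                    adj = list(2L, c(1L, 3L), c(2L, 4L), c(3L, 5L), 4L),
                    coords = co[1:5, ])
  vd@delaunay@points <- LocalizationSet(co)
  vd@delaunay@dupMap <- c(1:5, 2L)
  cr <- extractClusters(vd, c(TRUE, TRUE, TRUE, FALSE, FALSE), minLocs = 1L)
  expect_equal(nClusters(cr), 1L)
  expect_setequal(cr@members[[1]], c(1L, 2L, 3L, 6L))
  expect_equal(cr@clusters$nLocs, 4L)
  expect_equal(cr@clusters$volume, 3)  # duplicate shares its generator cell
})

test_that("cluster matching pairs by overlap and averages volume error", {
  mk <- function(members, vols) {
    df <- data.frame(id = seq_along(members),
                     nLocs = lengths(members), volume = vols,
                     barycenter.x = seq_along(members))
    new("ClusteringResult",
        threshold = new("VoronoiThreshold", yStar = 1, sStar = 1,
                        meanSize = 1, nullKind = "manual"),
        selected = logical(), clusters = df, members = members,
        parameters = list())
  }
  a <- mk(list(1:10, 11:20, 21:30, 31:40), c(100, 200, 300, 400))
  expect_equal(matchClusters(a, a)$meanVolumeDiff, 0)
  b <- mk(list(1:10, 11:20, 21:30, 31:40), c(102, 200, 300, 400))
  expect_equal(matchClusters(a, b)$meanVolumeDiff, 0.5)
  expect_equal(matchClusters(a, b)$pairs$b, 1:4)
  expect_warning(m0 <- matchClusters(a, mk(list(), numeric())))
  expect_true(is.na(m0$meanVolumeDiff))
})

test_that("density-factor segmentation matches its threshold equivalent", {
  locs <- randomLocs(4000, dim = 3, seed = 71, side = 2000)
  vd <- buildVoronoi(locs)
  # alpha = 1 on a uniform cloud selects about the CDF-at-1 fraction
  sr <- segmentByDensityFactor(vd, alpha = 1, minLocs = 1L)
  frac <- sum(sr@selected) / sum(!isBorder(vd))
  expect_equal(frac, pgamma(1, shape = 5, rate = 5), tolerance = 0.05)
  # alpha -> infinity selects nothing
  expect_equal(nClusters(segmentByDensityFactor(vd, alpha = 1e12)), 0L)
  # equivalence with an explicit threshold at <S>/alpha
  thr <- new("VoronoiThreshold", yStar = 1 / 2, sStar = meanCellSize(vd) / 2,
             meanSize = meanCellSize(vd), nullKind = "manual")
  cr <- extractClusters(vd, selectCells(vd, thr), minLocs = 5L)
  sr2 <- segmentByDensityFactor(vd, alpha = 2, minLocs = 5L)
  expect_identical(sr2@members, cr@members)
  expect_equal(sr2@clusters$volume, cr@clusters$volume)
})

test_that("selection grows monotonically with the threshold", {
  locs <- randomLocs(1500, dim = 3, seed = 72)
  vd <- buildVoronoi(locs)
  meanS <- meanCellSize(vd)
  prev <- rep(FALSE, length(cellSizes(vd)))
  for (y in c(0.2, 0.5, 1, 2, 5)) {
    cur <- selectCells(vd, y * meanS)
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("cluster volumes are invariant to row permutation", {
  cfg <- clusterSimConfig(nClusters = 4, locsPerCluster = 120, seed = 73,
                          bounds = boundingBox(c(0, 0, 0), rep(1500, 3)))
  locs <- simulateClustered(cfg)
  cr <- clusterVisu(locs, null = "analytical")
  set.seed(74)
  perm <- sample(nLocs(locs))
  locsP <- LocalizationSet(locCoords(locs)[perm, ], bounds = locBounds(locs))
  crP <- clusterVisu(locsP, null = "analytical")
  expect_equal(sort(crP@clusters$volume), sort(cr@clusters$volume),
               tolerance = 1e-9)
  expect_equal(nClusters(crP), nClusters(cr))
})

test_that("well-separated planted clusters are recovered exactly", {
  # dense compact clusters, wide separation, background well below the
  # cluster density but dense enough to cap the outward reach of
  # cluster-surface cells (see the methods vignette)
  cfg <- clusterSimConfig(nClusters = 5, profile = "uniform_sphere",
                          radius = 60, locsPerCluster = 5000,
                          backgroundFraction = 0.3, minSep = 1200,
                          margin = 400,
                          bounds = boundingBox(rep(0, 3), rep(4000, 3)),
                          seed = 75)
  locs <- simulateClustered(cfg)
  truth <- split(seq_len(nLocs(locs)), locExtras(locs)$label)
  truth <- truth[names(truth) != "0"]
  cr <- clusterVisu(locs, null = "analytical")
  expect_equal(nClusters(cr), 5L)
  jac <- vapply(truth, function(g) {
    ov <- vapply(cr@members, function(m) length(intersect(m, g)), 1L)
    best <- which.max(ov)
    length(intersect(cr@members[[best]], g)) /
      length(union(cr@members[[best]], g))
  }, 1)
  expect_gte(min(jac), 0.99)
})

test_that("MC and analytical thresholds agree on the same data", {
  cfg <- clusterSimConfig(nClusters = 6, locsPerCluster = 300, seed = 77,
                          bounds = boundingBox(c(0, 0, 0), rep(1600, 3)))
  locs <- simulateClustered(cfg)
  vd <- buildVoronoi(locs)
  emp <- cellSizePDF(vd)
  thrA <- findThreshold(emp, analyticalNull(3))
  mc <- monteCarloNull(length(cellSizes(vd)), locBounds(locs), nSims = 50L,
                       seed = 78)
  thrM <- findThreshold(emp, mc)
  expect_lt(abs(thrA@yStar - thrM@yStar) / thrM@yStar, 0.05)
})

test_that("uniform data yield the no-cluster-signal condition end to end", {
  locs <- randomLocs(1200, dim = 3, seed = 79, side = 1500)
  expect_error(clusterVisu(locs, null = "analytical"),
               class = "vc_no_cluster_signal_error")
})
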