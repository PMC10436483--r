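test_that("uniform simulations are exact, bounded and reproducible", {
  b <- boundingBox(c(0, 0, 0), rep(1000, 3))
  locs <- simulateUniform(100, b, seed = 5)
  expect_equal(nLocs(locs), 100L)
  co <- locCoords(locs)
  expect_true(all(co >= 0 & co <= 1000))
  expect_identical(locCoords(simulateUniform(100, b, seed = 5)), co)
  expect_false(identical(locCoords(simulateUniform(100, b, seed = 6)), co))
  expect_error(simulateUniform(0, b), class = "vc_input_error")
})

test_that("mean Poisson-Voronoi cell volume is the inverse intensity", {
  b <- boundingBox(c(0, 0, 0), rep(1, 3) * 1000)
  n <- 1e5
  locs <- simulateUniform(n, b, seed = 7)
  vd <- buildVoronoi(locs, clipBounds = locBounds(locs))
  expect_equal(meanCellSize(vd), boxMeasure(b) / n, tolerance = 0.02)
})

test_that("clustered simulations honor counts, labels and bounds", {
  cfg <- clusterSimConfig(nClusters = 20, locsPerCluster = 100,
                          nBackground = 0, seed = 8)
  locs <- simulateClustered(cfg)
  expect_equal(nLocs(locs), 2000L)
  expect_equal(unname(table(locExtras(locs)$label)), rep(100L, 20L),
               ignore_attr = TRUE)
  co <- locCoords(locs)
  b <- locBounds(locs)
  expect_true(all(t(co) >= b[1, ] & t(co) <= b[2, ]))
  # background counting: fraction of all localizations
  cfg2 <- clusterSimConfig(nClusters = 2, locsPerCluster = 450,
                           backgroundFraction = 0.1, seed = 9)
  locs2 <- simulateClustered(cfg2)
  expect_equal(nLocs(locs2), 1000L)
  expect_equal(sum(locExtras(locs2)$label == 0), 100L)
  # full determinism of coordinates and labels
  again <- simulateClustered(cfg2)
  expect_identical(locCoords(again), locCoords(locs2))
  expect_identical(locExtras(again)$label, locExtras(locs2)$label)
})

test_that("a single gaussian cluster matches its planted parameters", {
  cfg <- clusterSimConfig(nClusters = 1, locsPerCluster = 5000,
                          nBackground = 0, sigma = 50, seed = 10,
                          bounds = boundingBox(rep(0, 3), rep(4000, 3)))
  locs <- simulateClustered(cfg)
  expect_true(all(locExtras(locs)$label == 1))
  center <- locs@metadata$centers[1, ]
  bc <- colMeans(locCoords(locs))
  expect_true(all(abs(bc - center) < 3 * 50 / sqrt(5000)))
  cv <- cov(locCoords(locs))
  expect_equal(unname(diag(cv)), rep(2500, 3), tolerance = 0.1)
  expect_true(all(abs(cv[upper.tri(cv)]) < 150))
})

test_that("uniform-sphere clusters stay within their radius", {
  cfg <- clusterSimConfig(nClusters = 3, profile = "uniform_sphere",
                          radius = 80, locsPerCluster = 400,
                          nBackground = 0, seed = 11)
  locs <- simulateClustered(cfg)
  lab <- locExtras(locs)$label
  for (k in 1:3) {
    r <- sqrt(rowSums(sweep(locCoords(locs)[lab == k, ], 2L,
                            locs@metadata$centers[k, ])^2))
    expect_lte(max(r), 80)
    # uniform ball: E[r] = 3/4 R
    expect_equal(mean(r), 60, tolerance = 0.05)
  }
})

test_that("cluster centers respect separation, margin and feasibility", {
  cfg <- clusterSimConfig(nClusters = 10, locsPerCluster = 10, minSep = 600,
                          seed = 12)
  locs <- simulateClustered(cfg)
  ctr <- locs@metadata$centers
  dm <- as.matrix(dist(ctr))
  expect_gte(min(dm[dm > 0]), 600)
  expect_true(all(t(ctr) >= locBounds(locs)[1, ] + 150 - 1e-9))
  infeasible <- clusterSimConfig(nClusters = 60, locsPerCluster = 5,
                                 minSep = 900, seed = 13, maxTries = 500)
  expect_error(simulateClustered(infeasible), class = "vc_config_error")
})

test_that("planted clusters are denser than the background", {
  cfg <- clusterSimConfig(seed = 14)  # reference condition
  locs <- simulateClustered(cfg)
  expect_equal(nLocs(locs), 20L * 500L + round(0.1 / 0.9 * 10000))
  co <- locCoords(locs)
  ctr <- locs@metadata$centers
  # count points within 2 sigma of each center vs the uniform expectation
  vol2s <- 4 / 3 * pi * 100^3
  lambda_bg <- nLocs(locs) / boxMeasure(locBounds(locs))
  for (k in 1:5) {
    inside <- sum(sqrt(rowSums(sweep(co, 2L, ctr[k, ])^2)) < 100)
    expect_gt(inside, 20 * vol2s * lambda_bg)
  }
})
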