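test_that("normalizeSizes divides by the non-border mean", {
  expect_equal(as.numeric(normalizeSizes(c(2, 4, 6))), c(1/2, 1, 3/2))
  expect_equal(as.numeric(normalizeSizes(rep(3.3, 5))), rep(1, 5))
  y <- normalizeSizes(c(2, 4, 6), c(FALSE, FALSE, TRUE))
  expect_equal(as.numeric(y), c(2/3, 4/3))
  expect_equal(attr(y, "meanSize"), 3)
  expect_equal(mean(normalizeSizes(rgamma(100, 2))), 1)
  expect_error(normalizeSizes(1:3, rep(TRUE, 3)),
               class = "vc_empty_sample_error")
})

test_that("the closed-form densities are the stated gamma laws", {
  expect_equal(analyticalPDF(0, 3), 0)
  expect_equal(analyticalPDF(0, 2), 0)
  y <- seq(0, 8, by = 0.01)
  # independent route: gamma densities with the matching parameters
  expect_equal(analyticalPDF(y, 3), dgamma(y, shape = 5, rate = 5),
               tolerance = 1e-12)
  expect_equal(analyticalPDF(y, 2), dgamma(y, shape = 3.5, rate = 3.5),
               tolerance = 1e-12)
  # 2D normalizer equals (7/2)^(7/2)/Gamma(7/2), with Gamma(7/2)=15*sqrt(pi)/8
  expect_equal(343 / 15 * sqrt(7 / (2 * pi)),
               (7 / 2)^(7 / 2) / (15 * sqrt(pi) / 8), tolerance = 1e-12)
  expect_error(analyticalPDF(-0.1, 3), class = "vc_domain_error")
})

test_that("both analytical nulls integrate to one with unit mean", {
  for (d in 2:3) {
    f <- function(y) analyticalPDF(y, d)
    expect_lt(abs(integrate(f, 0, Inf, rel.tol = 1e-10)$value - 1), 1e-8)
    expect_lt(abs(integrate(function(y) y * f(y), 0, Inf,
                            rel.tol = 1e-10)$value - 1), 1e-8)
  }
  # 3D mode at y = 4/5
  opt <- optimize(function(y) analyticalPDF(y, 3), c(0, 3), maximum = TRUE,
                  tol = 1e-9)
  expect_equal(opt$maximum, 4 / 5, tolerance = 1e-6)
})

test_that("empiricalPDF builds a proper density histogram", {
  p <- empiricalPDF(rep(1, 100), breaks = seq(0, 2, by = 0.1))
  dens <- p@density
  expect_equal(sum(dens > 0), 1L)
  expect_equal(max(dens), 10)
  expect_equal(sum(dens * 0.1), 1)
  # dropped mass accounting
  p2 <- empiricalPDF(c(rep(0.5, 90), rep(9, 10)), breaks = seq(0, 2, 0.1))
  expect_equal(p2@droppedMass, 0.1)
  expect_equal(sum(p2@density * 0.1) + p2@droppedMass, 1)
  expect_error(empiricalPDF(1, breaks = c(1, 0.5)), class = "vc_input_error")
  expect_error(empiricalPDF(numeric()), class = "vc_empty_sample_error")
})

test_that("a large gamma sample reproduces the 3D analytical density", {
  set.seed(51)
  y <- rgamma(1e6, shape = 5, rate = 5)
  p <- empiricalPDF(y / mean(y))
  expect_lt(pdfDeviation(p, analyticalNull(3)), 1)
})

test_that("Monte-Carlo nulls are reproducible with contained envelopes", {
  b <- boundingBox(c(0, 0), c(1000, 1000))
  mc1 <- monteCarloNull(400, b, nSims = 4L, seed = 7)
  mc2 <- monteCarloNull(400, b, nSims = 4L, seed = 7)
  expect_identical(mc1@perSim, mc2@perSim)
  expect_true(all(mc1@lower <= mc1@meanDensity + 1e-12))
  expect_true(all(mc1@upper >= mc1@meanDensity - 1e-12))
  # single simulation: mean equals the simulation, envelope degenerate
  mc3 <- monteCarloNull(400, b, nSims = 1L, seed = 9)
  expect_equal(mc3@meanDensity, mc3@perSim[, 1])
  expect_equal(mc3@lower, mc3@upper)
  expect_equal(perSimPDF(mc3, 1)@density, mc3@meanDensity)
  # a different seed gives a different draw
  expect_false(identical(monteCarloNull(400, b, nSims = 1L, seed = 10)@perSim,
                         mc3@perSim))
})

test_that("the Monte-Carlo mean approaches the analytical law", {
  b3 <- boundingBox(c(0, 0, 0), rep(2000, 3))
  mc <- monteCarloNull(20000, b3, nSims = 3L, seed = 13)
  ctr <- (mc@breaks[-1] + mc@breaks[-length(mc@breaks)]) / 2
  ref <- analyticalPDF(ctr, 3)
  expect_lt(100 * mean(abs(mc@meanDensity - ref)) / max(ref), 5)
})

test_that("pdfDeviation measures percent-of-peak differences", {
  br <- seq(0, 1, by = 0.1)
  ref <- pdfFrom(br, rep(1, 10))
  expect_equal(pdfDeviation(ref, ref), 0)
  emp <- pdfFrom(br, rep(1.01, 10))
  expect_equal(pdfDeviation(emp, ref), 1, tolerance = 1e-9)
  expect_equal(pdfDeviation(emp, ref, "max_abs"), 1, tolerance = 1e-9)
})

test_that("two-sample tests behave canonically", {
  set.seed(61)
  a <- rnorm(100)
  r <- compareSamples(a, a, "ks")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  r2 <- compareSamples(1:10, 101:110, "ks")
  expect_equal(r2$statistic, 1)
  r3 <- compareSamples(rnorm(200), rnorm(200) + 1, "wilcoxon_rank")
  expect_lt(r3$p.value, 0.01)
  r4 <- compareSamples(rnorm(200), rnorm(200) + 1, "ks")
  expect_lt(r4$p.value, 0.01)
  expect_error(compareSamples(1, 1:5), class = "vc_input_error")
})
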