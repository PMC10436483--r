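test_that("CSV localization tables parse with the default dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "1,4,7", "2,5,8", "3,6,9"), f)
  locs <- readLocalizations(f)
  expect_equal(nLocs(locs), 3L)
  expect_equal(locDim(locs), 3L)
  expect_equal(unname(locCoords(locs)[, 1]), c(1, 2, 3))
  # 2-column file is read as 2D
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "3,4"), f2)
  expect_equal(locDim(readLocalizations(f2)), 2L)
})

test_that("micrometer input is converted to nanometers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "1,2,3"), f)
  locs <- readLocalizations(f, locDialect(unit = "um"))
  expect_equal(unname(locCoords(locs)[1, ]), c(1000, 2000, 3000))
})

test_that("the ThunderSTORM preset maps bracketed headers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","z [nm]"', "10,20,30"), f)
  locs <- readLocalizations(f, locDialect("thunderstorm"))
  expect_equal(unname(locCoords(locs)[1, ]), c(10, 20, 30))
})

test_that("write/read round trip preserves coordinates bit for bit", {
  set.seed(11)
  co <- matrix(runif(60) * 1e4 + runif(60), ncol = 3)
  locs <- LocalizationSet(co, extras = data.frame(frame = 1:20,
                                                  intensity = runif(20)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLocalizations(locs, f)
  back <- readLocalizations(f, locDialect(extras = c("frame", "intensity")))
  expect_identical(unname(locCoords(back)), unname(co))
  expect_equal(back@extras$frame, 1:20)
  expect_equal(back@extras$intensity, locs@extras$intensity)
  # extras columns appear after the coordinate columns, in declared order
  header <- strsplit(readLines(f, n = 1L), ",")[[1]]
  expect_identical(header, c("x", "y", "z", "frame", "intensity"))
})

test_that("malformed tables raise typed errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3"), f)
  expect_error(readLocalizations(f), class = "vc_format_error")
  writeLines(c("x,y,z", "1,2,3", "4,oops,6"), f)
  err <- tryCatch(readLocalizations(f), error = identity)
  expect_s3_class(err, "vc_parse_error")
  expect_match(conditionMessage(err), "row 2")
  writeLines("x,y,z", f)
  expect_error(readLocalizations(f), class = "vc_empty_input_error")
  expect_error(readLocalizations("/nonexistent/nowhere.csv"),
               class = "vc_io_error")
  expect_error(
    writeLocalizations(LocalizationSet(cbind(1, 2, 3)),
                       "/nonexistent-dir/out.csv"),
    class = "vc_io_error")
})

test_that("bounds contain the data and may only be enlarged", {
  co <- cbind(c(0, 10), c(0, 10), c(0, 10))
  locs <- LocalizationSet(co)
  expect_equal(unname(locBounds(locs)["lo", ]), c(0, 0, 0))
  big <- LocalizationSet(co, bounds = boundingBox(rep(-5, 3), rep(15, 3)))
  expect_equal(unname(locBounds(big)["hi", ]), rep(15, 3))
  expect_error(LocalizationSet(co, bounds = boundingBox(rep(1, 3),
                                                        rep(15, 3))))
})

test_that("the tight bounding box grows monotonically with added points", {
  set.seed(21)
  for (rep in 1:5) {
    co <- matrix(runif(30) * 100, ncol = 3)
    b1 <- locBounds(LocalizationSet(co))
    co2 <- rbind(co, runif(3) * 200 - 50)
    b2 <- locBounds(LocalizationSet(co2))
    expect_true(all(b2["lo", ] <= b1["lo", ]))
    expect_true(all(b2["hi", ] >= b1["hi", ]))
  }
})
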