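test_that("localization CSV round trip is the identity", {
  tab <- LocalizationTable(data.frame(
    x_nm = c(1.5, 2.25, 3), y_nm = c(0.5, 1, 1.5),
    z_nm = c(55.123456, 60.654321, 70.000001),
    channel = c("paxillin", "paxillin", "actin"),
    precision_nm = c(9, NA, 12)))
  f <- tempfile(fileext = ".csv")
  writeLocalizations(tab, f)
  back <- readLocalizations(f)
  expect_equal(nLocalizations(back), 3L)
  expect_identical(channelNames(back), c("actin", "paxillin"))
  expect_equal(locData(back)$z_nm, locData(tab)$z_nm, tolerance = 1e-6)
  expect_equal(locData(back)$id, locData(tab)$id)
  expect_true(is.na(locData(back)$precision_nm[2]))
})

test_that("empty tables round trip to header-only files", {
  f <- tempfile(fileext = ".csv")
  writeLocalizations(LocalizationTable(), f)
  expect_length(readLines(f), 1L)
  back <- readLocalizations(f)
  expect_equal(nLocalizations(back), 0L)
  expect_length(channelNames(back), 0L)
})

test_that("CSV reading reports format and parse errors precisely", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,channel", "1,2,a"), f)
  expect_error(readLocalizations(f), "z_nm")
  writeLines(c("x_nm,y_nm,z_nm", "1,2,3", "1,oops,3"), f)
  expect_error(readLocalizations(f), "row 2")
  expect_error(readLocalizations(tempfile()), "not found")
})

test_that("a dialect mapping ingests foreign column names", {
  f <- tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","z [nm]"', "100,200,55"), f)
  tab <- readLocalizations(f, dialect = c(x_nm = "x [nm]", y_nm = "y [nm]",
                                          z_nm = "z [nm]"))
  expect_equal(locData(tab)$z_nm, 55)
})

test_that("selectRoi keeps interior and boundary points, preserving order", {
  tab <- LocalizationTable(data.frame(
    x_nm = c(0.5, 2, 1, 0), y_nm = c(0.5, 2, 0, 0.25),
    z_nm = 1:4, channel = "a"))
  roi <- RoiRegion("sq", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "fa")
  sel <- selectRoi(tab, roi)
  # interior point, edge point (1, 0) and vertex-edge point (0, 0.25) retained
  expect_equal(locData(sel)$id, c(1L, 3L, 4L))
  # idempotent
  expect_equal(locData(selectRoi(sel, roi)), locData(sel))
})

test_that("ROI selection commutes with channel filtering", {
  set.seed(11)
  tab <- LocalizationTable(data.frame(
    x_nm = runif(200, -1, 2), y_nm = runif(200, -1, 2), z_nm = rnorm(200),
    channel = sample(c("a", "b"), 200, TRUE)))
  roi <- squareRoi(1)
  both <- selectRoi(tab, roi, channel = "a")
  other <- selectRoi(selectRoi(tab, roi), roi, channel = "a")
  expect_equal(locData(both)$id, locData(other)$id)
  expect_error(selectRoi(tab, roi, channel = "nope"), "unknown channel")
})

test_that("an ROI enclosing all points returns the identical table", {
  tab <- LocalizationTable(makeLocDf(10))
  sel <- selectRoi(tab, squareRoi(10000))
  expect_equal(locData(sel), locData(tab))
})

test_that("RoiRegion validity rejects degenerate polygons", {
  expect_error(RoiRegion("r", cbind(c(0, 1), c(0, 1))), "3 vertices")
  # bow-tie self-intersection
  expect_error(RoiRegion("r", cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))), "simple")
})

test_that("ROI JSON round trips", {
  rois <- list(squareRoi(500, "r1", "fa"), discRoi(300, 12L, "r2", "fa_adjacent"))
  f <- tempfile(fileext = ".json")
  writeRois(rois, f)
  back <- readRois(f)
  expect_equal(back[[1]]@polygon, rois[[1]]@polygon)
  expect_equal(back[[2]]@klass, "fa_adjacent")
})

test_that("renderDensity places points in half-open pixels and conserves counts", {
  one <- LocalizationTable(data.frame(x_nm = 25, y_nm = 35, z_nm = 0,
                                      channel = "a"))
  img <- renderDensity(one, pixel_nm = 10, bounds = c(0, 100, 0, 100))
  expect_equal(sum(img), 1L)
  expect_equal(img[4, 3], 1L)  # row = y bin 4, col = x bin 3
  n <- 7L
  co <- LocalizationTable(data.frame(x_nm = rep(25, n), y_nm = rep(35, n),
                                     z_nm = 0, channel = "a"))
  expect_equal(max(renderDensity(co, 10, c(0, 100, 0, 100))), n)
  set.seed(3)
  tab <- LocalizationTable(data.frame(x_nm = runif(500, 0, 100),
                                      y_nm = runif(500, 0, 100), z_nm = 0,
                                      channel = "a"))
  expect_equal(sum(renderDensity(tab, 7, c(0, 100, 0, 100))), 500L)
  expect_error(renderDensity(tab, 7, c(0, 0, 0, 100)), "degenerate")
  expect_error(renderDensity(tab, -1, c(0, 1, 0, 1)), "pixel_nm")
})
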