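test_that("line profiles normalize and localize intensity", {
  img <- matrix(1, 20, 20)
  attr(img, "pixel_nm") <- 10
  attr(img, "bounds") <- c(0, 200, 0, 200)
  flat <- lineProfile(img, c(15, 100), c(185, 100), width = 30)
  expect_true(all(abs(flat@values - 1) < 1e-12))
  img2 <- matrix(0, 20, 20)
  img2[10, 10] <- 5  # x in [90,100), y in [90,100)
  attr(img2, "pixel_nm") <- 10
  attr(img2, "bounds") <- c(0, 200, 0, 200)
  pk <- lineProfile(img2, c(5, 95), c(195, 95), width = 10)
  expect_equal(sum(pk@values == 1), 1L)
  expect_true(all(pk@values[pk@values < 1] == 0))
  expect_error(lineProfile(img2, c(5, 5), c(195, 5), width = 10),
               "all-zero")
})

test_that("an edge-ring adhesion profiles high at both ends of a diameter", {
  ring <- simulateLocalizations(
    LayerSpec("b5", 60, 8, lateral = "edge_ring", radius_nm = 1000,
              rim_width_nm = 150, count = 40000), seed = 2)
  img <- renderDensity(ring, pixel_nm = 50, bounds = c(0, 2000, 0, 2000))
  pr <- lineProfile(img, c(25, 1000), c(1975, 1000), width = 200)
  n <- length(pr@values)
  ends <- c(pr@values[1:3], pr@values[(n - 2):n])
  centre <- pr@values[(n %/% 2 - 1):(n %/% 2 + 1)]
  expect_gt(max(pr@values[1:5]), 0.5)
  expect_gt(max(pr@values[(n - 4):n]), 0.5)
  expect_lt(mean(centre), 0.5 * max(ends))
})

test_that("uniform discs give rim/interior ratios near 1", {
  roi <- discRoi(1000, 64L)
  tab <- simulateLocalizations(LayerSpec("x", 60, 8, radius_nm = 1000,
                                         count = 20000), seed = 3)
  ee <- edgeEnrichment(tab, roi, rim_width = 200)
  # MC sd of the ratio ~ sqrt(1/n_rim + 1/n_int)
  mcsd <- sqrt(1 / ee$rim_count + 1 / ee$interior_count)
  expect_lt(abs(ee$ratio - 1), 3 * mcsd + 0.02)  # + grid-area slack
})

test_that("rim-only and interior-only clouds hit the sentinels", {
  roi <- discRoi(1000, 64L)
  rim <- simulateLocalizations(
    LayerSpec("x", 60, 8, lateral = "edge_ring", radius_nm = 990,
              rim_width_nm = 100, count = 2000), seed = 4)
  expect_warning(ee <- edgeEnrichment(rim, roi, rim_width = 200), "empty interior")
  expect_identical(ee$ratio, Inf)
  inner <- simulateLocalizations(LayerSpec("x", 60, 8, radius_nm = 400,
                                           count = 2000), seed = 5)
  rec <- locData(inner)  # recentre the 400-nm disc on the ROI centre
  rec$x_nm <- rec$x_nm + 600; rec$y_nm <- rec$y_nm + 600
  expect_equal(edgeEnrichment(LocalizationTable(rec), roi,
                              rim_width = 200)$ratio, 0)
  expect_error(edgeEnrichment(inner, roi, rim_width = 2000), "half-extent")
})

test_that("edge enrichment is invariant under rigid motion", {
  roi <- discRoi(1000, 64L)
  tab <- simulateLocalizations(
    LayerSpec("x", 60, 8, lateral = "edge_ring", radius_nm = 1000,
              rim_width_nm = 300, count = 20000), seed = 6)
  e0 <- edgeEnrichment(tab, roi, rim_width = 200)$ratio
  th <- 0.7; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rec <- locData(tab)
  xy <- cbind(rec$x_nm, rec$y_nm) %*% rot
  rec$x_nm <- xy[, 1] + 5000; rec$y_nm <- xy[, 2] - 3000
  pg <- roi@polygon %*% rot
  roi2 <- RoiRegion("r", cbind(pg[, 1] + 5000, pg[, 2] - 3000), "fa")
  e1 <- edgeEnrichment(LocalizationTable(rec), roi2, rim_width = 200)$ratio
  expect_lt(abs(e1 - e0) / e0, 0.02)
})

test_that("paraboloid fits reproduce exact surfaces to machine precision", {
  set.seed(7)
  x <- runif(50, -500, 500); y <- runif(50, -500, 500)
  plane <- LocalizationTable(data.frame(x_nm = x, y_nm = y,
                                        z_nm = 5 + 0.1 * x, channel = "a"))
  pf <- fitParaboloid(plane)
  expect_true(pf@flat)
  expect_equal(unname(pf@coefficients[c("c3", "c4", "c5")]), c(0, 0, 0),
               tolerance = 1e-10)
  expect_equal(unname(pf@coefficients["c1"]), 0.1, tolerance = 1e-10)
  k <- 1e-4
  cup <- LocalizationTable(data.frame(x_nm = x, y_nm = y,
                                      z_nm = 80 + k * (x^2 + y^2),
                                      channel = "a"))
  cf <- fitParaboloid(cup)
  expect_equal(cf@curvatures, c(2e-4, 2e-4), tolerance = 1e-10)
  expect_false(cf@flat)
})

test_that("rank-deficient and tiny clouds are rejected", {
  x <- 1:10
  line <- LocalizationTable(data.frame(x_nm = x, y_nm = 2 * x, z_nm = x,
                                       channel = "a"))
  expect_error(fitParaboloid(line), "rank-deficient")
  expect_error(fitParaboloid(LocalizationTable(makeLocDf(5))), "6 points")
})

test_that("cup-model vinculin recovers its curvature; flat paxillin does not cup", {
  ks <- numeric(10)
  for (s in 1:10) {
    cup <- simulateLocalizations(
      LayerSpec("vinculin_N", 100.4, 14.4, lateral = "cup", cup_k = 1e-4,
                radius_nm = 1000, count = 5000), seed = s)
    ks[s] <- mean(fitParaboloid(cup)@curvatures) / 2  # curvature = 2k
  }
  expect_lt(median(abs(ks - 1e-4) / 1e-4), 0.10)
  flat <- fitParaboloid(simulateLocalizations(
    LayerSpec("paxillin", 55.7, 8.5, radius_nm = 1000, count = 20000),
    seed = 3))
  expect_true(flat@flat)
})
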