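test_that("single-component generator matches its moments", {
  spec <- LayerSpec("x", 100, 15, count = 20000)
  z <- locData(simulateLocalizations(spec, seed = 42))$z_nm
  expect_lt(abs(mean(z) - 100), 3 * 15 / sqrt(20000))
  expect_lt(abs(sd(z) - 15) / 15, 0.05)
})

test_that("generation is bit-reproducible by seed and varies across seeds", {
  spec <- LayerSpec("x", 100, 15, count = 500)
  a <- simulateLocalizations(spec, seed = 7)
  b <- simulateLocalizations(spec, seed = 7)
  expect_identical(locData(a), locData(b))
  c <- simulateLocalizations(spec, seed = 8)
  expect_false(identical(locData(a)$z_nm, locData(c)$z_nm))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulateLocalizations(spec, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("count = 0 yields an empty table", {
  expect_equal(nLocalizations(simulateLocalizations(
    LayerSpec("x", 100, 15, count = 0), seed = 1)), 0L)
})

test_that("bimodal actin layers produce two separated histogram peaks", {
  tab <- simulateLocalizations(referenceLayerSpec("actin"), seed = 3)
  h <- zHistogram(tab)
  s <- nanoFA:::.smooth3(as.numeric(h@counts))
  mids <- nanoFA:::.binCentres(h)
  low <- mids > 80 & mids < 120
  high <- mids > 135 & mids < 175
  trough <- mids >= 120 & mids <= 135
  expect_gt(max(s[low]), 1.5 * min(s[trough]))
  expect_gt(max(s[high]), 1.5 * min(s[trough]))
})

test_that("mixture component fractions converge to the weights", {
  spec <- LayerSpec("x", c(50, 150), c(2, 2), weight = c(0.3, 0.7),
                    count = 50000)
  z <- locData(simulateLocalizations(spec, seed = 5))$z_nm
  fracLow <- mean(z < 100)
  expect_lt(abs(fracLow - 0.3), 3 * sqrt(0.3 * 0.7 / 50000))
})

test_that("background fraction adds a uniform z floor", {
  spec <- LayerSpec("x", 100, 5, count = 50000, background_fraction = 0.2,
                    background_z_range = c(0, 300))
  z <- locData(simulateLocalizations(spec, seed = 6))$z_nm
  fracFar <- mean(z < 50 | z > 150)  # essentially only background lands here
  expect_lt(abs(fracFar - 0.2 * 200 / 300), 0.02)
})

test_that("lateral geometries respect their radii", {
  R <- 1000
  ring <- simulateLocalizations(
    LayerSpec("x", 100, 5, lateral = "edge_ring", radius_nm = R,
              rim_width_nm = 150, count = 5000), seed = 2)
  r <- with(locData(ring), sqrt((x_nm - R)^2 + (y_nm - R)^2))
  expect_gte(min(r), R - 150 - 1e-9)
  expect_lte(max(r), R + 1e-9)
  disc <- simulateLocalizations(
    LayerSpec("x", 100, 5, radius_nm = R, count = 5000), seed = 2)
  rd <- with(locData(disc), sqrt((x_nm - R)^2 + (y_nm - R)^2))
  # uniform by area: median radius at R/sqrt(2)
  expect_lt(abs(median(rd) - R / sqrt(2)) / R, 0.02)
})

test_that("hyper-exponential area samples have the analytic mean", {
  a <- simulateAreas(0.8, 4.2, w = 1, n = 20000, seed = 1)
  expect_lt(abs(mean(a) - 0.8), 4 * 0.8 / sqrt(20000))
  b <- simulateAreas(0.8, 4.2, w = 0, n = 50000, seed = 2)
  expect_lt(abs(mean(b) - 4.2), 4 * 4.2 / sqrt(50000))
  cc <- simulateAreas(1, 3, w = 0.25, n = 50000, seed = 3)
  expected <- 0.25 * 1 + 0.75 * 3
  expect_lt(abs(mean(cc) - expected), 4 * sd(cc) / sqrt(50000))
  expect_error(simulateAreas(4.2, 0.8, 0.5, 10, 1), "a1 < a2")
  expect_identical(simulateAreas(1, 2, 0.5, 100, 9),
                   simulateAreas(1, 2, 0.5, 100, 9))
})

test_that("colony movies carry exact ground truth", {
  mv <- simulateColonyMovie(ColonySpec(nEdgeFa = 4L, nCentreFa = 6L),
                            MovieSpec(nFrames = 12L, centreBirthRate = 0),
                            seed = 11)
  # edge adhesions persist the whole movie
  edge <- mv$truth[mv$truth$klass == "edge", ]
  expect_true(all(edge$birth_frame == 1L & edge$death_frame == 12L))
  # per-frame areas agree with direct pixel counting
  f <- 6L
  tb <- table(mv$stack[, , f][mv$stack[, , f] > 0])
  fa <- mv$frameAreas[mv$frameAreas$frame == f, ]
  expect_equal(fa$area_um2[order(fa$adhesion_id)],
               as.numeric(tb) * mv$pixelUm^2)
  # labels stay inside the colony
  expect_true(all(mv$colonyMask[mv$stack[, , f] > 0]))
  # determinism
  mv2 <- simulateColonyMovie(ColonySpec(nEdgeFa = 4L, nCentreFa = 6L),
                             MovieSpec(nFrames = 12L, centreBirthRate = 0),
                             seed = 11)
  expect_identical(mv$stack, mv2$stack)
})

test_that("label stacks round trip through 16-bit TIFF", {
  mv <- simulateColonyMovie(ColonySpec(nEdgeFa = 3L, nCentreFa = 4L),
                            MovieSpec(nFrames = 3L, centreBirthRate = 0),
                            seed = 4)
  f <- tempfile(fileext = ".tif")
  writeLabelStack(mv$stack, f)
  expect_identical(readLabelStack(f), mv$stack)
})

test_that("invalid specs are rejected", {
  expect_error(LayerSpec("x", 100, -1), "s_vert")
  expect_error(LayerSpec("x", c(1, 2), c(1, 1), weight = c(0.6, 0.6)), "sum to 1")
  expect_error(LayerSpec("x", 100, 15, background_fraction = 1), "backgroundFraction")
  expect_error(ColonySpec(areaModel = list(
    edge = list(a1 = 5, a2 = 4, w = 0.5),
    centre = list(a1 = 0.5, a2 = 1.8, w = 0.5))), "a1 < a2")
  expect_error(MovieSpec(nFrames = 0L), "nFrames")
})
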