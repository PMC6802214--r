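test_that("histograms use half-open 1-nm bins and conserve counts", {
  h <- zHistogram(c(10.2, 10.7))
  expect_equal(sum(h@counts > 0), 1L)
  expect_equal(h@counts[which(h@binEdges == 10)], 2L)
  # a value exactly on an edge belongs to the bin starting there
  h2 <- zHistogram(c(10.5, 11.0), range = c(10, 12))
  expect_equal(as.integer(h2@counts), c(1L, 1L))
  # conservation for random input, including a max exactly on an edge
  set.seed(21)
  z <- c(round(runif(500, 0, 50), 3), 50)
  expect_equal(zHistogram(z)@nTotal, 501L)
  expect_error(zHistogram(numeric(0)), "explicit range")
  expect_error(zHistogram(z, bin_width = 0), "bin_width")
})

test_that("single-Gaussian fits agree with sample moments across seeds", {
  for (seed in 1:10) {
    tab <- simulateLocalizations(LayerSpec("x", 100, 15, count = 20000),
                                 seed = seed)
    z <- locData(tab)$z_nm
    fit <- fitGaussianLayer(zHistogram(tab))
    expect_true(isConverged(fit))
    expect_lt(abs(zCentre(fit) - mean(z)), 1)
    expect_lt(abs(sVert(fit) - sd(z)) / sd(z), 0.03)
  }
})

test_that("fit preconditions are enforced", {
  h <- zHistogram(rep(c(1.5, 2.5, 3.5, 4.5, 5.5), 20))
  expect_error(fitGaussianLayer(zHistogram(rep(1.5, 100))), "occupied bins")
  expect_error(fitGaussianLayer(zHistogram(c(1.5, 2.5, 3.5, 4.5, 5.5))),
               "50 localizations")
  expect_s4_class(fitGaussianLayer(h), "LayerFit")
})

test_that("the core fit resolves a symmetric two-bin profile to its centre", {
  # equal counts at bin centres 99.5 and 100.5, zero-padded elsewhere:
  # symmetry forces mu = 100
  x <- seq(95.5, 104.5, by = 1)
  y <- rep(0, 10); y[x == 99.5] <- 40; y[x == 100.5] <- 40
  core <- nanoFA:::.fitGaussianCore(x, y, 1)
  expect_equal(unname(core$par["mu"]), 100, tolerance = 1e-6)
})

test_that("two-Gaussian fits recover well-separated near-delta peaks", {
  spec <- LayerSpec("x", c(50, 150), c(2, 2), count = 20000)
  tab <- simulateLocalizations(spec, seed = 13)
  z <- locData(tab)$z_nm
  fit <- fitTwoGaussianLayers(zHistogram(tab))
  # component-wise sample means are the construction oracle
  expect_lt(abs(zCentre(fit)[1] - mean(z[z < 100])), 0.5)
  expect_lt(abs(zCentre(fit)[2] - mean(z[z >= 100])), 0.5)
  expect_false(isDegenerate(fit))
  expect_equal(sum(componentWeights(fit)), 1)
})

test_that("components are reported low-then-high regardless of init", {
  tab <- simulateLocalizations(referenceLayerSpec("actin"), seed = 17)
  h <- zHistogram(tab)
  a <- fitTwoGaussianLayers(h, init = c(99.6, 155.4))
  b <- fitTwoGaussianLayers(h, init = c(155.4, 99.6))
  expect_equal(zCentre(a), zCentre(b), tolerance = 1e-6)
  expect_true(all(diff(zCentre(a)) > 0))
})

test_that("identical overlapping components trigger the degeneracy flag", {
  tab <- simulateLocalizations(LayerSpec("x", c(100, 100), c(15, 15),
                                         count = 20000), seed = 19)
  fit <- fitTwoGaussianLayers(zHistogram(tab))
  expect_true(isDegenerate(fit))
  expect_lt(abs(diff(zCentre(fit))), max(sVert(fit)) / 2)
})

test_that("model selection keeps one layer for unimodal data", {
  tab <- simulateLocalizations(LayerSpec("x", 100, 15, count = 20000),
                               seed = 23)
  sel <- selectLayerModel(zHistogram(tab))
  expect_equal(sel$modelOrder, 1L)
})

test_that("model selection finds the two actin layers", {
  sel <- selectLayerModel(zHistogram(
    simulateLocalizations(referenceLayerSpec("actin"), seed = 29)))
  expect_equal(sel$modelOrder, 2L)
  expect_lt(abs(zCentre(sel$fit2)[1] - 99.6), 3)
  expect_lt(abs(zCentre(sel$fit2)[2] - 155.4), 3)
})

test_that("sparse noise defaults to one layer with a low-confidence note", {
  tab <- simulateLocalizations(LayerSpec("x", 150, 80, count = 60), seed = 31)
  sel <- selectLayerModel(zHistogram(tab))
  expect_equal(sel$modelOrder, 1L)
  expect_match(sel$note, "low-confidence")
})

test_that("summaries combine fits with box statistics", {
  mk <- function(zc) methods::new("LayerFit", modelOrder = 1L, zCentre = zc,
                                  sVert = 10, weight = 1, amplitude = 100,
                                  rss = 0, bic = 0, nTotal = 1000L,
                                  converged = TRUE, degenerate = FALSE,
                                  note = character(0))
  one <- summarizeLayers(list(mk(10)), "p")
  expect_equal(one@stats$mean_z, 10)
  expect_equal(one@stats$q3_z - one@stats$q1_z, 0)   # IQR = 0 for one ROI
  two <- summarizeLayers(list(mk(10), mk(20)), "p")
  expect_equal(two@stats$mean_z, 15)
  expect_equal(two@stats$median_z, 15)
  expect_equal(two@stats$whisker_high,
               two@stats$median_z + 1.5 * (two@stats$q3_z - two@stats$q1_z))
  bad <- methods::new("LayerFit", modelOrder = 2L, zCentre = c(1, 2),
                      sVert = c(1, 1), weight = c(0.5, 0.5),
                      amplitude = c(1, 1), rss = 0, bic = 0, nTotal = 100L,
                      converged = TRUE, degenerate = FALSE,
                      note = character(0))
  expect_error(summarizeLayers(list(mk(10), bad)), "same model order")
})

test_that("many-ROI summaries recover the paxillin layer", {
  fits <- lapply(1:23, function(s) fitReference("paxillin", seed = 100 + s,
                                                count = 2000L))
  sm <- summarizeLayers(fits, "paxillin")
  expect_equal(sm@nRois, 23L)
  expect_lt(abs(unname(zCentre(sm)) - 55.7), 2)
})
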