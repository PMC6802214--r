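test_that("a static blob yields one track spanning all frames", {
  st <- staticBlobStack(nFrames = 7L)
  ts <- trackAdhesions(st, pixel_um = 0.1, frame_interval_min = 1)
  tr <- trackTable(ts)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$birth_frame, 1)
  expect_equal(tr$death_frame, 7)
})

test_that("never-overlapping blobs produce separate tracks", {
  st <- array(0L, dim = c(20, 20, 3))
  st[3:4, 3:4, ] <- 1L
  st[15:16, 15:16, 1:2] <- 2L   # disappears after frame 2
  ts <- trackAdhesions(st, pixel_um = 1)
  tr <- trackTable(ts)
  expect_equal(nrow(tr), 2L)
  expect_equal(sort(tr$death_frame), c(2, 3))
  # a one-frame disappearance ends a track: reappearance starts a new one
  st2 <- array(0L, dim = c(10, 10, 3))
  st2[3:4, 3:4, 1] <- 1L
  st2[3:4, 3:4, 3] <- 1L
  expect_equal(nrow(trackTable(trackAdhesions(st2, pixel_um = 1))), 2L)
})

test_that("per-frame label identity changes do not break tracks", {
  st <- array(0L, dim = c(10, 10, 3))
  st[3:5, 3:5, 1] <- 7L
  st[3:5, 3:5, 2] <- 2L   # same region, different frame-local label
  st[4:6, 3:5, 3] <- 9L   # shifted but overlapping
  ts <- trackAdhesions(st, pixel_um = 1)
  expect_equal(nrow(trackTable(ts)), 1L)
  expect_equal(nrow(ts@frameAreas), 3L)
})

test_that("splits keep the identity on the largest fragment", {
  st <- array(0L, dim = c(12, 20, 2))
  st[4:9, 4:15, 1] <- 1L
  st[4:9, 4:10, 2] <- 1L    # large fragment (42 px)
  st[4:6, 13:15, 2] <- 2L   # small fragment (9 px)
  ts <- trackAdhesions(st, pixel_um = 1)
  tr <- trackTable(ts)
  fa <- ts@frameAreas
  cont <- fa$track_id[fa$frame == 2 & fa$area_um2 == 42]
  expect_equal(cont, 1L)               # big fragment continues track 1
  expect_equal(nrow(tr), 2L)           # small fragment starts a new track
})

test_that("every labeled pixel belongs to exactly one track", {
  mv <- simulateColonyMovie(ColonySpec(nEdgeFa = 4L, nCentreFa = 8L),
                            MovieSpec(nFrames = 15L), seed = 51)
  ts <- trackAdhesions(mv$stack, pixel_um = mv$pixelUm,
                       edge_mask = mv$edgeMask, centre_mask = mv$centreMask)
  fa <- ts@frameAreas
  for (f in c(1L, 8L, 15L)) {
    fg <- sum(mv$stack[, , f] > 0) * mv$pixelUm^2
    expect_equal(sum(fa$area_um2[fa$frame == f]), fg)
  }
})

test_that("generator tracks are recovered with exact birth and death", {
  mv <- simulateColonyMovie(ColonySpec(nEdgeFa = 5L, nCentreFa = 10L),
                            MovieSpec(nFrames = 30L), seed = 53)
  ts <- trackAdhesions(mv$stack, pixel_um = mv$pixelUm,
                       edge_mask = mv$edgeMask, centre_mask = mv$centreMask)
  tr <- trackTable(ts)
  m <- merge(tr, mv$truth, by.x = "track_id", by.y = "adhesion_id")
  expect_equal(nrow(m), nrow(mv$truth))
  frac <- mean(m$birth_frame.x == m$birth_frame.y &
               m$death_frame.x == m$death_frame.y)
  expect_gte(frac, 0.95)
  expect_equal(m$klass.x, m$klass.y)
})

test_that("lifetimes are capped at 105 min and frequencies normalize", {
  st <- staticBlobStack(nFrames = 200L, dim = c(12L, 12L))
  ts <- trackAdhesions(st, pixel_um = 1, frame_interval_min = 1)
  ts@tracks$klass <- "edge"
  d <- lifetimeDistribution(ts, cap_min = 105)
  expect_equal(sum(d$freq), 1)
  expect_equal(d$bin_lo[d$freq > 0], 90)   # 105 min lands in the [90, 105) -> capped top bin
  expect_lte(max(d$bin_hi), 105)
  # capping is idempotent
  d2 <- lifetimeDistribution(ts, cap_min = 105)
  expect_equal(d, d2)
  # short track: 5 frames at 1 min/frame -> 5 min
  ts5 <- trackAdhesions(staticBlobStack(5L), pixel_um = 1)
  ts5@tracks$klass <- "centre"
  d5 <- lifetimeDistribution(ts5, cap_min = 105, bin_width = 1)
  expect_equal(d5$bin_lo[d5$freq > 0], 5)  # lifetime 5 min in bin [5, 6)
})

test_that("maximal-size distributions normalize per class", {
  mv <- simulateColonyMovie(ColonySpec(nEdgeFa = 4L, nCentreFa = 8L),
                            MovieSpec(nFrames = 10L), seed = 55)
  ts <- trackAdhesions(mv$stack, pixel_um = mv$pixelUm,
                       edge_mask = mv$edgeMask, centre_mask = mv$centreMask)
  d <- maxSizeDistribution(ts, bin_um2 = 0.5)
  for (kl in unique(d$klass))
    expect_equal(sum(d$freq[d$klass == kl]), 1)
})

test_that("coverage fractions match direct pixel accounting", {
  st <- array(0L, dim = c(10, 10, 2))
  edge <- matrix(FALSE, 10, 10); edge[1:2, ] <- TRUE       # 20 px
  centre <- matrix(FALSE, 10, 10); centre[5:8, 5:8] <- TRUE  # 16 px
  st[1, , 1] <- 1L                                          # half the edge
  cv <- coverageFraction(st, edge, centre)
  expect_equal(cv$edge_pct, c(50, 0))
  expect_equal(cv$centre_pct, c(0, 0))
  expect_error(coverageFraction(st, edge, edge), "disjoint")
  expect_warning(coverageFraction(st, matrix(FALSE, 10, 10), centre),
                 "edge mask")
})

test_that("synthetic movies show stable edges and dynamic centres", {
  mv <- simulateColonyMovie(ColonySpec(nEdgeFa = 6L, nCentreFa = 12L),
                            MovieSpec(nFrames = 60L), seed = 57)
  ts <- trackAdhesions(mv$stack, pixel_um = mv$pixelUm,
                       edge_mask = mv$edgeMask, centre_mask = mv$centreMask)
  tr <- trackTable(ts)
  life <- (tr$death_frame - tr$birth_frame + 1) * ts@frameIntervalMin
  expect_gt(median(life[tr$klass == "edge"]),
            median(life[tr$klass == "centre"]))
  cv <- coverageFraction(mv$stack, mv$edgeMask, mv$centreMask)
  gt <- 100 * sum(mv$stack[, , 60] > 0 & mv$edgeMask) / sum(mv$edgeMask)
  expect_equal(cv$edge_pct[60], gt)
})

test_that("mismatched frame shapes are rejected", {
  maps <- list(
    segmentAdhesions(matrix(0, 5, 5), pixel_um = 1),
    segmentAdhesions(matrix(0, 6, 6), pixel_um = 1))
  expect_error(trackAdhesions(maps), "mismatched")
})
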