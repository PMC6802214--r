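# Shared fixture builders: everything is generated in code at test time.

# Minimal localization data.frame around a given z layer.
makeLocDf <- function(n = 5, z = 100, channel = "paxillin") {
  data.frame(x_nm = seq_len(n) * 10, y_nm = seq_len(n) * 5,
             z_nm = rep(z, n), channel = channel)
}

# Square ROI [0, side] x [0, side] in nm.
squareRoi <- function(side = 1000, label = "fa1", klass = "fa") {
  RoiRegion(label, cbind(c(0, side, side, 0), c(0, 0, side, side)), klass)
}

# Regular polygon approximating the generator's lateral disc
# (radius R centred at (R, R)).
discRoi <- function(R = 1000, nV = 64L, label = "disc", klass = "fa") {
  ang <- seq(0, 2 * pi, length.out = nV + 1L)[-(nV + 1L)]
  RoiRegion(label, cbind(R + R * cos(ang), R + R * sin(ang)), klass)
}

# Single-component ProteinSummary with a stated mean z (for geometry tests).
summaryAt <- function(mean_z, protein = "p", mean_svert = 10) {
  s <- data.frame(component = "single", mean_z = mean_z, sd_z = 0,
                  median_z = mean_z, q1_z = mean_z, q3_z = mean_z,
                  whisker_low = mean_z, whisker_high = mean_z,
                  mean_svert = mean_svert, sd_svert = 0)
  methods::new("ProteinSummary", protein = protein, modelOrder = 1L,
               stats = s, nRois = 1L)
}

# Simulate a protein at its reference layer values and fit the 1-nm
# histogram (single Gaussian).
fitReference <- function(protein, seed, count = 20000L) {
  tab <- simulateLocalizations(referenceLayerSpec(protein, count = count),
                               seed = seed)
  fitGaussianLayer(zHistogram(tab))
}

# Label stack with one static rectangular blob over nFrames.
staticBlobStack <- function(nFrames = 5L, dim = c(30L, 30L)) {
  img <- matrix(0L, dim[1], dim[2])
  img[5:9, 5:9] <- 1L
  array(rep(img, nFrames), dim = c(dim, nFrames))
}
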