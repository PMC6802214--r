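# Synthetic-data generators: layered localization clouds, hyper-exponential
# adhesion-area samples, and colony movies with stable edge / dynamic centre
# adhesions. These provide the ground truth every downstream stage is tested
# against. Each generator consumes an explicit seed and leaves the caller's
# RNG stream untouched.

#' Construct a LayerSpec
#'
#' @param protein channel label.
#' @param z_centre,s_vert,weight vectors of per-component vertical Gaussian
#'   parameters (nm, nm, fractions summing to 1).
#' @param lateral lateral geometry: `uniform_disc`, `edge_ring`, `cup`,
#'   `wall`, or `uniform_annulus`.
#' @param radius_nm disc/annulus outer radius.
#' @param rim_width_nm annulus width for `edge_ring`, `wall` and
#'   `uniform_annulus`.
#' @param cup_k cup curvature: `k * r^2` nm is added to z at lateral radius
#'   `r` nm (`cup` geometry only).
#' @param wall_offset_nm vertical offset added to z for the `wall` geometry.
#' @param count number of localizations.
#' @param background_fraction fraction of localizations drawn uniformly in z
#'   over `background_z_range` and uniformly in the lateral disc, emulating
#'   the cytoplasmic fraction around an adhesion.
#' @param background_z_range nm range of the uniform background.
#' @return A [LayerSpec-class].
#' @examples
#' LayerSpec("paxillin", 55.7, 8.5, count = 20000)
#' LayerSpec("actin", c(99.6, 155.4), c(14.4, 14.2), c(0.5, 0.5))
#' @export
LayerSpec <- function(protein, z_centre, s_vert, weight = NULL,
                      lateral = "uniform_disc", radius_nm = 1000,
                      rim_width_nm = 200, cup_k = 0, wall_offset_nm = 0,
                      count = 20000L, background_fraction = 0,
                      background_z_range = c(0, 300)) {
  k <- length(z_centre)
  if (is.null(weight)) weight <- rep(1 / k, k)
  cmp <- data.frame(z_centre = z_centre, s_vert = s_vert, weight = weight)
  methods::new("LayerSpec", protein = protein, components = cmp,
               lateral = lateral,
               lateralParams = list(radius_nm = radius_nm,
                                    rim_width_nm = rim_width_nm,
                                    cup_k = cup_k,
                                    wall_offset_nm = wall_offset_nm),
               count = as.integer(count),
               backgroundFraction = background_fraction,
               backgroundZRange = background_z_range)
}

#' Reference layer parameters of hPSC cornerstone focal adhesions
#'
#' The per-protein vertical layer parameters (`Z_centre`, `s_vert`, both nm)
#' reported for cornerstone focal adhesions of human pluripotent stem cell
#' colonies: the integrin-signalling layer (paxillin), the force-transduction
#' layer (N-/C-terminally tagged talin-1 and vinculin), the two actin and
#' two alpha-actinin-1 layers, and the kank1/kank2 wall positions adjacent
#' and distal to adhesions. These are the study conditions the synthetic
#' generator emulates and the recovery tests run at.
#'
#' @return data.frame with columns `protein`, `component`, `z_centre`,
#'   `s_vert`.
#' @examples
#' cornerstoneLayers()
#' @export
cornerstoneLayers <- function() {
  data.frame(
    protein = c("paxillin", "talin1_N", "talin1_C", "vinculin_N",
                "vinculin_C", "actin", "actin", "alpha_actinin1",
                "alpha_actinin1", "kank1_adjacent", "kank1_distal",
                "kank2_adjacent", "kank2_distal"),
    component = c("single", "single", "single", "single", "single",
                  "low", "high", "low", "high",
                  "single", "single", "single", "single"),
    z_centre = c(55.7, 72.8, 103.5, 100.4, 76.4, 99.6, 155.4, 125.5, 174.8,
                 116.1, 63.4, 100.8, 74.2),
    s_vert = c(8.5, 12, 20.5, 14.4, 16.3, 14.4, 14.2, 15.1, 17.1,
               12.1, 13.6, 13.4, 17.7),
    stringsAsFactors = FALSE)
}

#' LayerSpec at the reference parameters of one protein
#'
#' Convenience wrapper around [LayerSpec()] and [cornerstoneLayers()]:
#' builds the generative spec for a protein at its reported layer values
#' (both components for the bimodal actin / alpha-actinin-1 profiles,
#' equal weights).
#'
#' @param protein a protein name from [cornerstoneLayers()].
#' @param count localizations to draw.
#' @param ... passed to [LayerSpec()].
#' @return A [LayerSpec-class].
#' @export
referenceLayerSpec <- function(protein, count = 20000L, ...) {
  ref <- cornerstoneLayers()
  rows <- ref[ref$protein == protein, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown protein '", protein, "'; see cornerstoneLayers()")
  LayerSpec(protein, rows$z_centre, rows$s_vert, count = count, ...)
}

# Draw lateral radii uniform by area on [r0, r1].
.annulusRadii <- function(n, r0, r1) sqrt(r0^2 + stats::runif(n) * (r1^2 - r0^2))

#' Generate a layered localization table
#'
#' Draws `count` localizations: each non-background record picks a vertical
#' component with its weight and draws z from that component's Gaussian;
#' lateral position follows the named geometry (uniform disc, edge ring =
#' uniform annulus `[R - rim, R]`, cup = disc with `k r^2` added to z, wall =
#' rim annulus with a vertical offset). Background records are uniform in z
#' over the spec's range and uniform in the lateral disc. Identical
#' `(spec, seed)` gives a bit-identical table.
#'
#' @param spec a [LayerSpec-class].
#' @param seed integer seed (mandatory: generators own their RNG stream).
#' @return A [LocalizationTable-class] with `meta$seed` recorded.
#' @examples
#' tab <- simulateLocalizations(LayerSpec("paxillin", 55.7, 8.5, count = 1000),
#'                              seed = 7)
#' mean(locData(tab)$z_nm)
#' @export
simulateLocalizations <- function(spec, seed) {
  stopifnot(methods::is(spec, "LayerSpec"))
  methods::validObject(spec)
  n <- spec@count
  if (n == 0L)
    return(LocalizationTable(meta = list(seed = seed, protein = spec@protein)))
  lp <- spec@lateralParams
  R <- lp$radius_nm
  withSeed(seed, {
    isbg <- stats::runif(n) < spec@backgroundFraction
    cmp <- spec@components
    comp <- sample.int(nrow(cmp), n, replace = TRUE, prob = cmp$weight)
    z <- stats::rnorm(n, cmp$z_centre[comp], cmp$s_vert[comp])
    theta <- stats::runif(n, 0, 2 * pi)
    r <- switch(spec@lateral,
      uniform_disc = .annulusRadii(n, 0, R),
      cup          = .annulusRadii(n, 0, R),
      edge_ring    = .annulusRadii(n, max(R - lp$rim_width_nm, 0), R),
      wall         = .annulusRadii(n, max(R - lp$rim_width_nm, 0), R),
      uniform_annulus = .annulusRadii(n, max(R - lp$rim_width_nm, 0), R))
    if (spec@lateral == "cup") z <- z + lp$cup_k * r^2
    if (spec@lateral == "wall") z <- z + lp$wall_offset_nm
    if (any(isbg)) {
      nb <- sum(isbg)
      z[isbg] <- stats::runif(nb, spec@backgroundZRange[1],
                              spec@backgroundZRange[2])
      r[isbg] <- .annulusRadii(nb, 0, R)
    }
    rec <- data.frame(x_nm = R + r * cos(theta), y_nm = R + r * sin(theta),
                      z_nm = z, channel = spec@protein,
                      stringsAsFactors = FALSE)
    LocalizationTable(rec, meta = list(seed = seed, protein = spec@protein,
                                       lateral = spec@lateral))
  })
}

#' Sample adhesion areas from a hyper-exponential model
#'
#' Each draw comes from `Exponential(mean a1)` with probability `w` and from
#' `Exponential(mean a2)` otherwise — the weighted sum of two exponential
#' densities used as the adhesion-area model, with characteristic areas
#' `a1 < a2` (the ordering is the identifiability convention).
#'
#' @param a1,a2 characteristic areas in um^2, `a1 < a2`.
#' @param w mixture weight of the `a1` component, in `[0, 1]`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric vector of `n` areas (um^2).
#' @examples
#' a <- simulateAreas(0.8, 4.2, w = 0.6, n = 1000, seed = 1)
#' mean(a)  # close to 0.6 * 0.8 + 0.4 * 4.2
#' @export
simulateAreas <- function(a1, a2, w, n, seed) {
  if (a1 >= a2) stop("require a1 < a2 (ordering is the identifiability convention)")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (n < 0) stop("n must be >= 0")
  if (n == 0L) return(numeric(0))
  withSeed(seed, {
    from1 <- stats::runif(n) < w
    ifelse(from1, stats::rexp(n, rate = 1 / a1), stats::rexp(n, rate = 1 / a2))
  })
}

#' Construct a ColonySpec
#'
#' Defaults describe a 256 x 256 px field at 0.2 um/px holding a roughly
#' circular colony (radius 20 um), a 5-um edge strip, a dozen large stable
#' cornerstone adhesions at the edge and a larger number of smaller dynamic
#' adhesions at the centre. Maximal adhesion sizes are drawn from
#' hyper-exponential models with characteristic areas `a2` = 4.2 um^2 (edge)
#' and 1.8 um^2 (centre).
#'
#' @param imageShape c(rows, cols) in pixels.
#' @param pixelUm micrometres per pixel.
#' @param colonyPolygon n x 2 vertex matrix in pixel coordinates; default a
#'   24-gon disc centred in the field.
#' @param edgeStripUm edge-strip thickness (um).
#' @param nEdgeFa,nCentreFa initial adhesion counts per class.
#' @param areaModel list(edge = list(a1, a2, w), centre = list(a1, a2, w)).
#' @return A [ColonySpec-class].
#' @export
ColonySpec <- function(imageShape = c(256L, 256L), pixelUm = 0.2,
                       colonyPolygon = NULL, edgeStripUm = 5,
                       nEdgeFa = 12L, nCentreFa = 25L,
                       areaModel = list(edge = list(a1 = 0.8, a2 = 4.2, w = 0.6),
                                        centre = list(a1 = 0.5, a2 = 1.8, w = 0.6))) {
  if (is.null(colonyPolygon)) {
    cx <- (imageShape[2] + 1) / 2
    cy <- (imageShape[1] + 1) / 2
    rad <- 0.78 * min(imageShape) / 2
    ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
    colonyPolygon <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  }
  methods::new("ColonySpec", imageShape = as.integer(imageShape),
               pixelUm = pixelUm, colonyPolygon = as.matrix(colonyPolygon),
               edgeStripUm = edgeStripUm, nEdgeFa = as.integer(nEdgeFa),
               nCentreFa = as.integer(nCentreFa), areaModel = areaModel)
}

#' Construct a MovieSpec
#'
#' Defaults emulate a 105-minute movie at one frame per minute: edge
#' adhesions are born at the first frame and persist; centre adhesions are
#' born throughout (Poisson births per frame) and die after exponential
#' lifetimes with a 25-minute mean.
#'
#' @param nFrames number of frames.
#' @param frameIntervalMin minutes between frames.
#' @param centreLifetimeMeanMin mean centre-adhesion lifetime (minutes).
#' @param centreBirthRate expected centre births per frame.
#' @param growthFrames frames to reach maximal size (log-linear growth).
#' @return A [MovieSpec-class].
#' @export
MovieSpec <- function(nFrames = 105L, frameIntervalMin = 1,
                      centreLifetimeMeanMin = 25, centreBirthRate = 0.3,
                      growthFrames = 5L) {
  methods::new("MovieSpec", nFrames = as.integer(nFrames),
               frameIntervalMin = frameIntervalMin,
               centreLifetimeMeanMin = centreLifetimeMeanMin,
               centreBirthRate = centreBirthRate,
               growthFrames = as.integer(growthFrames))
}

# Rasterize one ellipse (centre cx, cy px; semi-axes a, b px; angle phi) into
# label image `img`, restricted to `mask`, leaving existing labels in place.
.paintEllipse <- function(img, mask, cx, cy, a, b, phi, label) {
  if (a <= 0 || b <= 0) return(img)
  rr <- max(1L, floor(cy - a)):min(nrow(img), ceiling(cy + a))
  cc <- max(1L, floor(cx - a)):min(ncol(img), ceiling(cx + a))
  if (length(rr) == 0L || length(cc) == 0L) return(img)
  dx <- outer(rep(1, length(rr)), cc - cx)
  dy <- outer(rr - cy, rep(1, length(cc)))
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[rr, cc, drop = FALSE]
  msub <- mask[rr, cc, drop = FALSE]
  paint <- inside & msub & sub == 0L
  sub[paint] <- label
  img[rr, cc] <- sub
  img
}

#' Generate a synthetic colony adhesion movie
#'
#' Renders elliptical adhesions into a labeled image stack: edge adhesions
#' sit in the colony's edge strip, appear at frame 1, grow log-linearly to
#' their maximal size and persist (stable cornerstone behaviour); centre
#' adhesions are born over time and disappear after exponential lifetimes
#' (dynamic behaviour). Labels are stable across frames for the same
#' adhesion. Maximal sizes come from the per-class hyper-exponential area
#' models. Placement keeps adhesions disjoint so overlap tracking can be
#' validated against the returned ground truth.
#'
#' @param colony a [ColonySpec-class].
#' @param movie a [MovieSpec-class].
#' @param seed integer seed.
#' @return list with `stack` (integer array rows x cols x frames of adhesion
#'   labels), `truth` (data.frame `adhesion_id`, `klass`, `birth_frame`,
#'   `death_frame`, `max_area_um2` — realized pixel areas), `frameAreas`
#'   (long data.frame `adhesion_id`, `frame`, `area_um2`), `colonyMask`,
#'   `edgeMask`, `centreMask` (logical matrices), `pixelUm`,
#'   `frameIntervalMin`.
#' @export
simulateColonyMovie <- function(colony, movie, seed) {
  stopifnot(methods::is(colony, "ColonySpec"), methods::is(movie, "MovieSpec"))
  methods::validObject(colony)
  methods::validObject(movie)
  nr <- colony@imageShape[1]; nc <- colony@imageShape[2]
  px <- colony@pixelUm
  cc <- rep(seq_len(nc), each = nr)
  rr <- rep(seq_len(nr), times = nc)
  colonyMask <- matrix(pointsInPolygon(cc, rr, colony@colonyPolygon[, 1],
                                       colony@colonyPolygon[, 2]), nr, nc)
  part <- partitionEdgeCentre(colonyMask, strip = colony@edgeStripUm,
                              pixel_um = px)
  colonyAreaUm2 <- sum(colonyMask) * px^2
  nF <- movie@nFrames
  withSeed(seed, {
    draws <- list()
    mkAdhesions <- function(klass, n, births) {
      if (n == 0L) return(NULL)
      m <- colony@areaModel[[klass]]
      from1 <- stats::runif(n) < m$w
      maxArea <- ifelse(from1, stats::rexp(n, 1 / m$a1), stats::rexp(n, 1 / m$a2))
      if (any(maxArea > colonyAreaUm2))
        stop("generated adhesion area exceeds colony area")
      if (klass == "edge") {
        deaths <- rep(nF, n)
      } else {
        lifeFrames <- pmax(1L, ceiling(stats::rexp(n, 1 / movie@centreLifetimeMeanMin) /
                                         movie@frameIntervalMin))
        deaths <- pmin(nF, births + lifeFrames - 1L)
      }
      data.frame(klass = klass, birth = births, death = deaths,
                 max_area_um2 = maxArea,
                 aspect = stats::runif(n, 1.5, 2.5),
                 phi = stats::runif(n, 0, pi))
    }
    edge <- mkAdhesions("edge", colony@nEdgeFa, rep(1L, colony@nEdgeFa))
    cen0 <- mkAdhesions("centre", colony@nCentreFa, rep(1L, colony@nCentreFa))
    nLate <- stats::rpois(nF - 1L, movie@centreBirthRate)
    lateBirths <- rep(seq.int(2L, length.out = nF - 1L), nLate)
    late <- mkAdhesions("centre", length(lateBirths), as.integer(lateBirths))
    adh <- rbind(edge, cen0, late)
    adh$adhesion_id <- seq_len(nrow(adh))
    # place centres: class pixels, rejection sampling for disjointness
    adh$amax <- sqrt(adh$max_area_um2 / px^2 * adh$aspect / pi)
    adh$cx <- NA_real_; adh$cy <- NA_real_
    for (i in seq_len(nrow(adh))) {
      mask <- if (adh$klass[i] == "edge") part$edge else part$centre
      cand <- which(mask)
      if (length(cand) == 0L) stop("empty class region; enlarge the colony")
      placed <- FALSE
      for (try in seq_len(400L)) {
        p <- cand[sample.int(length(cand), 1L)]
        y <- ((p - 1L) %% nr) + 1L
        x <- ((p - 1L) %/% nr) + 1L
        prev <- which(!is.na(adh$cx[seq_len(i - 1L)]))
        if (length(prev) == 0L ||
            all(sqrt((adh$cx[prev] - x)^2 + (adh$cy[prev] - y)^2) >
                adh$amax[prev] + adh$amax[i] + 2)) {
          adh$cx[i] <- x; adh$cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed) stop("could not place adhesions disjointly; reduce counts or areas")
    }
    stack <- array(0L, dim = c(nr, nc, nF))
    for (f in seq_len(nF)) {
      img <- matrix(0L, nr, nc)
      active <- which(adh$birth <= f & adh$death >= f)
      for (i in active) {
        tsb <- f - adh$birth[i] + 1L
        frac <- min(1, log1p(tsb) / log1p(movie@growthFrames))
        a <- sqrt(adh$max_area_um2[i] / px^2 * adh$aspect[i] / pi) * sqrt(frac)
        b <- a / adh$aspect[i]
        img <- .paintEllipse(img, colonyMask, adh$cx[i], adh$cy[i], a, b,
                             adh$phi[i], adh$adhesion_id[i])
      }
      stack[, , f] <- img
    }
    # realized ground truth from the rendered stack
    fa <- do.call(rbind, lapply(seq_len(nF), function(f) {
      tb <- table(stack[, , f][stack[, , f] > 0L])
      if (length(tb) == 0L) return(NULL)
      data.frame(adhesion_id = as.integer(names(tb)), frame = f,
                 area_um2 = as.numeric(tb) * px^2)
    }))
    if (is.null(fa)) fa <- data.frame(adhesion_id = integer(0),
                                      frame = integer(0), area_um2 = numeric(0))
    realized <- fa[fa$adhesion_id > 0L, , drop = FALSE]
    agg <- if (nrow(realized)) {
      data.frame(adhesion_id = sort(unique(realized$adhesion_id)))
    } else data.frame(adhesion_id = integer(0))
    if (nrow(agg)) {
      agg$birth_frame <- vapply(agg$adhesion_id, function(id)
        min(realized$frame[realized$adhesion_id == id]), integer(1))
      agg$death_frame <- vapply(agg$adhesion_id, function(id)
        max(realized$frame[realized$adhesion_id == id]), integer(1))
      agg$max_area_um2 <- vapply(agg$adhesion_id, function(id)
        max(realized$area_um2[realized$adhesion_id == id]), numeric(1))
      agg$klass <- adh$klass[match(agg$adhesion_id, adh$adhesion_id)]
      agg <- agg[, c("adhesion_id", "klass", "birth_frame", "death_frame",
                     "max_area_um2")]
    }
    list(stack = stack, truth = agg, frameAreas = realized,
         colonyMask = colonyMask, edgeMask = part$edge,
         centreMask = part$centre, pixelUm = px,
         frameIntervalMin = movie@frameIntervalMin, seed = seed)
  })
}

#' Write / read a labeled image stack as 16-bit TIFF
#'
#' Labels are stored in a multi-page 16-bit grayscale TIFF (one page per
#' frame). `readLabelStack` restores the integer array.
#'
#' @param stack integer array rows x cols x frames (or a matrix for a single
#'   frame), labels < 65536.
#' @param path TIFF file path.
#' @return `writeLabelStack` invisibly returns `path`; `readLabelStack`
#'   returns an integer array.
#' @export
writeLabelStack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (max(stack) > 65535L) stop("labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) stack[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelStack
#' @export
readLabelStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  out <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) out[, , f] <- as.integer(round(pages[[f]] * 65535))
  out
}
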