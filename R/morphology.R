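# Adhesion morphology: segmentation of 2D adhesion-marker images,
# edge/centre partition of colony masks, and the hyper-exponential
# (two-exponential mixture) model of adhesion areas fitted by EM.

#' Segment adhesions from a grayscale image
#'
#' Global threshold (Otsu by default, on the image rescaled to `[0, 1]`)
#' followed by 8-connected component labeling; regions below `min_area_um2`
#' are removed. Areas are pixel counts times `pixel_um^2`. When edge/centre
#' masks are supplied each adhesion is classified by majority pixel overlap
#' (ties go to edge).
#'
#' @param image numeric matrix (grayscale) or path to a TIFF file.
#' @param pixel_um micrometres per pixel (> 0).
#' @param min_area_um2 minimum adhesion area (default 0.05).
#' @param threshold `"otsu"` or a fixed numeric threshold on the raw image;
#'   pixels strictly above it are foreground.
#' @param edge_mask,centre_mask optional logical matrices from
#'   [partitionEdgeCentre()] used to set each adhesion's class.
#' @return An [AdhesionMap-class]. A blank image yields an empty map.
#' @export
segmentAdhesions <- function(image, pixel_um, min_area_um2 = 0.05,
                             threshold = "otsu", edge_mask = NULL,
                             centre_mask = NULL) {
  if (is.character(image)) image <- tiff::readTIFF(image)
  stopifnot(is.matrix(image))
  if (!is.numeric(pixel_um) || pixel_um <= 0) stop("pixel_um must be > 0")
  rng <- range(image)
  if (identical(threshold, "otsu")) {
    if (rng[2] > rng[1]) {
      scaled <- (image - rng[1]) / (rng[2] - rng[1])
      th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
      fg <- scaled > th
    } else {
      fg <- matrix(FALSE, nrow(image), ncol(image))  # constant image: blank
    }
  } else {
    fg <- image > threshold
  }
  lab <- labelComponents8(fg)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    minPix <- min_area_um2 / pixel_um^2
    keep <- which(sizes >= minPix)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  labs <- sort(unique(lab[lab > 0L]))
  tab <- if (length(labs)) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    rr <- ((idx - 1L) %% nrow(lab)) + 1L
    cc <- ((idx - 1L) %/% nrow(lab)) + 1L
    npix <- tabulate(l, nbins = max(l))
    klass <- rep(NA_character_, length(labs))
    if (!is.null(edge_mask) && !is.null(centre_mask)) {
      ne <- vapply(labs, function(k) sum(edge_mask[idx[l == k]]), numeric(1))
      ncn <- vapply(labs, function(k) sum(centre_mask[idx[l == k]]), numeric(1))
      klass <- ifelse(ne >= ncn, "edge", "centre")
      klass[ne + ncn == 0] <- NA_character_
    }
    data.frame(label = labs, area_um2 = npix[labs] * pixel_um^2,
               x_px = vapply(labs, function(k) mean(cc[l == k]), numeric(1)),
               y_px = vapply(labs, function(k) mean(rr[l == k]), numeric(1)),
               klass = klass, stringsAsFactors = FALSE)
  } else {
    data.frame(label = integer(0), area_um2 = numeric(0), x_px = numeric(0),
               y_px = numeric(0), klass = character(0),
               stringsAsFactors = FALSE)
  }
  methods::new("AdhesionMap", labels = lab, table = tab, pixelUm = pixel_um)
}

#' Partition a colony mask into edge strip and centre
#'
#' The edge is the set of colony pixels within `strip` of the colony
#' boundary (computed from the distance transform, with the image border
#' counting as boundary); the centre is the remainder. The two masks are
#' disjoint and their union is the colony.
#'
#' @param colony_mask logical (or 0/1) matrix; must be non-empty.
#' @param strip strip thickness, in pixels, or in micrometres when
#'   `pixel_um` is given. The two standard presets are 40 px (fixed-cell
#'   analysis) and 5 um (live analysis).
#' @param pixel_um optional micrometres per pixel; when supplied, `strip`
#'   is interpreted in micrometres.
#' @return list with logical matrices `edge` and `centre`. A warning is
#'   issued when the strip consumes the whole colony (empty centre).
#' @examples
#' m <- matrix(FALSE, 120, 120); m[11:110, 11:110] <- TRUE
#' p <- partitionEdgeCentre(m, strip = 10)
#' sum(p$edge)   # 3600
#' @export
partitionEdgeCentre <- function(colony_mask, strip, pixel_um = NULL) {
  mask <- colony_mask != 0
  if (!any(mask)) stop("colony mask is empty")
  if (strip <= 0) stop("strip must be positive")
  strip_px <- if (is.null(pixel_um)) strip else strip / pixel_um
  # pad so the image border counts as colony boundary
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  d <- EBImage::distmap(padded)
  d <- d[2:(nr + 1L), 2:(nc + 1L)]
  edge <- mask & d <= strip_px
  centre <- mask & !edge
  if (!any(centre))
    warning("strip consumes the whole colony: centre is empty")
  list(edge = edge, centre = centre)
}

# Log-likelihood of the two-exponential mixture at (w, a1, a2).
.hyperexpLogLik <- function(areas, w, a1, a2) {
  sum(log(w * stats::dexp(areas, 1 / a1) +
          (1 - w) * stats::dexp(areas, 1 / a2)))
}

# One EM run from a given start; returns parameters and loglik trace.
.emRun <- function(areas, w, a1, a2, max_iter, tol) {
  ll <- .hyperexpLogLik(areas, w, a1, a2)
  trace <- ll
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dexp(areas, 1 / a1)
    d2 <- (1 - w) * stats::dexp(areas, 1 / a2)
    r1 <- d1 / (d1 + d2)
    s1 <- sum(r1)
    if (s1 < 1e-12 || s1 > length(areas) - 1e-12) break  # collapsed weight
    wN <- s1 / length(areas)
    a1N <- sum(r1 * areas) / s1
    a2N <- sum((1 - r1) * areas) / (length(areas) - s1)
    llN <- .hyperexpLogLik(areas, wN, a1N, a2N)
    w <- wN; a1 <- a1N; a2 <- a2N
    trace <- c(trace, llN)
    if (llN - ll < tol * max(1, abs(llN))) { ll <- llN; break }
    ll <- llN
  }
  list(w = w, a1 = a1, a2 = a2, logLik = ll, trace = trace)
}

#' Fit the hyper-exponential adhesion-area model
#'
#' Maximum-likelihood fit of `w Exp(mean a1) + (1 - w) Exp(mean a2)` to raw
#' areas by expectation-maximization with 5 deterministic quantile-based
#' starts and best-likelihood selection. Components are reported with
#' `a1 < a2` (swapping `w` accordingly); standard errors come from the
#' numerically differentiated observed information. The EM log-likelihood
#' trace is retained and is non-decreasing by construction. Effectively
#' single-component data (relative `a1`/`a2` gap below 1% or a boundary
#' weight) is returned with a degeneracy flag rather than an error.
#'
#' @param areas numeric vector of adhesion areas (um^2), all positive,
#'   length >= 50.
#' @param max_iter maximum EM iterations per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @return An [AreaMixtureFit-class].
#' @examples
#' a <- simulateAreas(0.8, 4.2, w = 0.6, n = 5000, seed = 1)
#' fitAreaMixture(a)
#' @export
fitAreaMixture <- function(areas, max_iter = 500L, tol = 1e-10) {
  areas <- as.numeric(areas)
  if (length(areas) < 50L) stop("need at least 50 areas")
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("all areas must be positive and finite")
  m <- mean(areas)
  qs <- stats::quantile(areas, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- list(
    list(w = 0.5, a1 = qs[1], a2 = max(qs[3], qs[1] * 2)),
    list(w = 0.6, a1 = m / 3, a2 = m * 2),
    list(w = 0.3, a1 = m / 2, a2 = m * 3),
    list(w = 0.7, a1 = qs[2] / 2, a2 = qs[2] * 2),
    list(w = 0.5, a1 = m * 0.9, a2 = m * 1.1))
  best <- NULL
  for (st in starts) {
    run <- .emRun(areas, st$w, st$a1, st$a2, max_iter, tol)
    if (any(diff(run$trace) < -1e-8 * pmax(1, abs(run$trace[-1]))))
      stop("EM log-likelihood decreased: numerical failure")
    if (is.null(best) || run$logLik > best$logLik) best <- run
  }
  # ordering convention a1 < a2
  if (best$a1 > best$a2) {
    tmp <- best$a1; best$a1 <- best$a2; best$a2 <- tmp
    best$w <- 1 - best$w
  }
  degenerate <- (best$a2 - best$a1) / best$a2 < 0.01 ||
    best$w < 1e-4 || best$w > 1 - 1e-4
  se <- c(w = NA_real_, a1 = NA_real_, a2 = NA_real_)
  if (!degenerate) {
    nll <- function(p) -.hyperexpLogLik(areas, p[1], p[2], p[3])
    H <- tryCatch(pracma::hessian(nll, c(best$w, best$a1, best$a2)),
                  error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0))
        se <- stats::setNames(sqrt(diag(V)), c("w", "a1", "a2"))
    }
  }
  methods::new("AreaMixtureFit", a1 = best$a1, a2 = best$a2, w = best$w,
               se = se, logLik = best$logLik, n = length(areas),
               trace = best$trace, degenerate = degenerate)
}
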