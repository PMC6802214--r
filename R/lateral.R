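# Within-adhesion lateral architecture: normalized line intensity profiles,
# the rim/interior density ratio that operationalizes the edge-ring
# signature, and the quadratic (paraboloid) surface fit of 3D point clouds.

#' Normalized line intensity profile through an image
#'
#' Averages intensity perpendicular to a segment over a stated width,
#' sampled along the segment at pixel pitch, then divides by the maximum.
#' Coordinates are in nm; the image must carry a `pixel_nm` attribute (as
#' produced by [renderDensity()]) unless `pixel_nm` is given.
#'
#' @param image 2D numeric matrix (row = y, column = x).
#' @param p0,p1 segment endpoints, numeric `c(x, y)` in nm.
#' @param width averaging width in nm (>= 1 pixel).
#' @param pixel_nm pixel size in nm; defaults to `attr(image, "pixel_nm")`.
#' @return A [LineProfile-class].
#' @examples
#' img <- matrix(1, 10, 10)
#' attr(img, "pixel_nm") <- 10
#' attr(img, "bounds") <- c(0, 100, 0, 100)
#' lineProfile(img, c(5, 50), c(95, 50), width = 20)
#' @export
lineProfile <- function(image, p0, p1, width, pixel_nm = NULL) {
  pixel_nm <- pixel_nm %||% attr(image, "pixel_nm")
  if (is.null(pixel_nm)) stop("pixel_nm must be supplied or attached to the image")
  if (width < pixel_nm) stop("width must be at least one pixel")
  bounds <- attr(image, "bounds") %||% c(0, ncol(image) * pixel_nm,
                                         0, nrow(image) * pixel_nm)
  seglen <- sqrt(sum((p1 - p0)^2))
  if (seglen <= 0) stop("segment endpoints must differ")
  u <- (p1 - p0) / seglen                # along-segment unit vector
  v <- c(-u[2], u[1])                    # perpendicular unit vector
  tpos <- seq(0, seglen, by = pixel_nm)
  offs <- seq(-width / 2, width / 2, by = pixel_nm)
  vals <- vapply(tpos, function(t) {
    pts <- cbind(p0[1] + t * u[1] + offs * v[1],
                 p0[2] + t * u[2] + offs * v[2])
    jx <- floor((pts[, 1] - bounds[1]) / pixel_nm) + 1L
    iy <- floor((pts[, 2] - bounds[3]) / pixel_nm) + 1L
    ok <- jx >= 1L & jx <= ncol(image) & iy >= 1L & iy <= nrow(image)
    if (!any(ok)) return(NA_real_)
    mean(image[cbind(iy[ok], jx[ok])])
  }, numeric(1))
  keep <- !is.na(vals)
  if (!any(keep) || max(vals[keep]) <= 0)
    stop("all-zero strip: normalization undefined")
  tpos <- tpos[keep]
  vals <- vals[keep] / max(vals[keep])
  methods::new("LineProfile", positions = tpos, values = vals,
               endpoints = rbind(p0, p1), width = width)
}

#' Rim/interior localization density ratio of an adhesion
#'
#' Operationalizes "ring-ness": the ratio of localization density (count per
#' area) in the rim — points within `rim_width` of the ROI polygon boundary,
#' inside the polygon — to the density in the remaining interior. Uniform
#' clouds give a ratio near 1; edge-enriched proteins (integrin beta-5,
#' talin) give ratios above 1. Areas are computed on a fine grid
#' (deterministic), so the metric is invariant under rigid motions up to
#' grid resolution.
#'
#' @param table a [LocalizationTable-class].
#' @param fa a [RoiRegion-class] for the adhesion outline.
#' @param rim_width rim thickness in nm (default 200); must be smaller than
#'   the polygon's minimal half-extent.
#' @param grid_n grid resolution per axis for the area computation.
#' @return list with `ratio` (Inf with a warning when the interior is empty
#'   of area or localizations but the rim is not), `rim_count`,
#'   `interior_count`, `rim_area_nm2`, `interior_area_nm2`.
#' @export
edgeEnrichment <- function(table, fa, rim_width = 200, grid_n = 400L) {
  stopifnot(methods::is(table, "LocalizationTable"), methods::is(fa, "RoiRegion"))
  px <- fa@polygon[, 1]; py <- fa@polygon[, 2]
  bb <- c(range(px), range(py))
  if (rim_width >= min(diff(bb[1:2]), diff(bb[3:4])) / 2)
    stop("rim_width must be smaller than the polygon's minimal half-extent")
  rec <- locData(table)
  inside <- if (nrow(rec)) pointsInPolygon(rec$x_nm, rec$y_nm, px, py)
            else logical(0)
  xin <- rec$x_nm[inside]; yin <- rec$y_nm[inside]
  inRim <- distToPolygonBoundary(xin, yin, px, py) <= rim_width
  # areas by counting fine-grid cell centres
  gx <- seq(bb[1], bb[2], length.out = grid_n)
  gy <- seq(bb[3], bb[4], length.out = grid_n)
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  gpts <- expand.grid(x = gx, y = gy)
  gin <- pointsInPolygon(gpts$x, gpts$y, px, py)
  gd <- distToPolygonBoundary(gpts$x[gin], gpts$y[gin], px, py)
  rimArea <- sum(gd <= rim_width) * cell
  intArea <- sum(gd > rim_width) * cell
  nr <- sum(inRim); ni <- sum(!inRim)
  if (intArea <= 0 || (ni == 0 && nr > 0)) {
    warning("empty interior: returning infinite rim/interior ratio")
    ratio <- Inf
  } else if (ni == 0 && nr == 0) {
    ratio <- NA_real_
  } else {
    ratio <- (nr / rimArea) / (ni / intArea)
  }
  list(ratio = ratio, rim_count = nr, interior_count = ni,
       rim_area_nm2 = rimArea, interior_area_nm2 = intArea)
}

#' Fit a quadratic surface (paraboloid) to a 3D localization cloud
#'
#' Ordinary least squares of
#' `z = c0 + c1 x + c2 y + c3 x^2 + c4 xy + c5 y^2` on the localization
#' coordinates. Principal curvatures are the eigenvalues of the Hessian
#' `[[2 c3, c4], [c4, 2 c5]]`; positive curvature means a cup opening
#' upward (z increasing with lateral distance). A `flat` verdict is issued
#' when both |curvatures| fall below `flat_threshold`. Coordinates are
#' centred internally for conditioning; quadratic coefficients are invariant
#' under that translation, and `c0`..`c2` are mapped back to the original
#' frame.
#'
#' @param table a [LocalizationTable-class] with at least 6 points not all
#'   collinear.
#' @param flat_threshold curvature magnitude (1/nm) below which the surface
#'   counts as flat (default 1e-5).
#' @return A [SurfaceFit-class].
#' @examples
#' spec <- LayerSpec("vinculin_N", 100.4, 14.4, lateral = "cup",
#'                   cup_k = 1e-4, count = 5000)
#' fitParaboloid(simulateLocalizations(spec, seed = 1))
#' @export
fitParaboloid <- function(table, flat_threshold = 1e-5) {
  stopifnot(methods::is(table, "LocalizationTable"))
  rec <- locData(table)
  if (nrow(rec) < 6L) stop("need at least 6 points for a quadratic surface")
  x0 <- mean(rec$x_nm); y0 <- mean(rec$y_nm)
  x <- rec$x_nm - x0; y <- rec$y_nm - y0; z <- rec$z_nm
  X <- cbind(1, x, y, x^2, x * y, y^2)
  qrX <- qr(X)
  if (qrX$rank < 6L) stop("rank-deficient design: points are degenerate")
  beta <- qr.coef(qrX, z)
  res <- z - X %*% beta
  # map intercept/linear terms back to original coordinates
  c3 <- beta[4]; c4 <- beta[5]; c5 <- beta[6]
  c1 <- beta[2] - 2 * c3 * x0 - c4 * y0
  c2 <- beta[3] - 2 * c5 * y0 - c4 * x0
  c0 <- beta[1] - beta[2] * x0 - beta[3] * y0 + c3 * x0^2 + c4 * x0 * y0 +
    c5 * y0^2
  coefs <- stats::setNames(c(c0, c1, c2, c3, c4, c5), paste0("c", 0:5))
  H <- matrix(c(2 * c3, c4, c4, 2 * c5), 2, 2)
  curv <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  methods::new("SurfaceFit", coefficients = coefs, curvatures = curv,
               flat = all(abs(curv) < flat_threshold),
               rss = sum(res^2), nPoints = nrow(rec))
}
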