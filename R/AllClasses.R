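# Central S4 class definitions. Constructors live next to the module code
# that produces each object; accessors and show() methods are defined here.

LOC_COLUMNS <- c("id", "frame", "x_nm", "y_nm", "z_nm", "channel", "precision_nm")

ROI_CLASSES <- c("fa", "fa_adjacent", "fa_distal", "colony_edge",
                 "colony_centre", "other")

#' LocalizationTable: a point cloud of localized molecules
#'
#' One row per localized molecule with lateral (`x_nm`, `y_nm`) and vertical
#' (`z_nm`, distance from the coverslip) coordinates in nanometres, an
#' acquisition `frame`, a `channel` label (protein/fluorophore) and an optional
#' lateral localization `precision_nm`. This is the primary input of the
#' vertical-profile and lateral-architecture analyses.
#'
#' @slot records data.frame with columns `id`, `frame`, `x_nm`, `y_nm`,
#'   `z_nm`, `channel`, `precision_nm` (NA when unknown).
#' @slot meta free-form list (source file, generation seed, ...).
#' @export
setClass("LocalizationTable",
  representation(records = "data.frame", meta = "list"),
  prototype(records = data.frame(), meta = list()))

setValidity("LocalizationTable", function(object) {
  rec <- object@records
  if (nrow(rec) == 0L) return(TRUE)
  if (!all(LOC_COLUMNS %in% names(rec)))
    return(paste("records must have columns:", paste(LOC_COLUMNS, collapse = ", ")))
  if (anyDuplicated(rec$id)) return("localization ids must be unique")
  if (!all(is.finite(rec$x_nm)) || !all(is.finite(rec$y_nm)) ||
      !all(is.finite(rec$z_nm)))
    return("x_nm, y_nm, z_nm must be finite")
  if (any(rec$frame < 0)) return("frame must be non-negative")
  p <- rec$precision_nm
  if (any(!is.na(p) & p < 0)) return("precision_nm must be >= 0 when present")
  TRUE
})

#' RoiRegion: a labeled polygonal region of interest
#'
#' A simple (non-self-intersecting) polygon in nm coordinates with a label and
#' a region class: an individual focal adhesion (`fa`), FA-adjacent or
#' FA-distal surroundings, colony edge/centre, or `other`.
#'
#' @slot label character scalar.
#' @slot polygon two-column numeric matrix of vertices (x, y) in nm,
#'   at least 3 vertices, not closed (first vertex not repeated).
#' @slot klass one of `fa`, `fa_adjacent`, `fa_distal`, `colony_edge`,
#'   `colony_centre`, `other`.
#' @export
setClass("RoiRegion",
  representation(label = "character", polygon = "matrix", klass = "character"))

setValidity("RoiRegion", function(object) {
  pg <- object@polygon
  if (!is.numeric(pg) || ncol(pg) != 2L) return("polygon must be an n x 2 numeric matrix")
  if (nrow(pg) < 3L) return("polygon needs >= 3 vertices")
  if (!all(is.finite(pg))) return("polygon vertices must be finite")
  if (!object@klass %in% ROI_CLASSES)
    return(paste("klass must be one of:", paste(ROI_CLASSES, collapse = ", ")))
  if (!polygonIsSimple(pg[, 1], pg[, 2])) return("polygon must be simple")
  if (polygonArea(pg[, 1], pg[, 2]) <= 0) return("polygon must enclose positive area")
  TRUE
})

#' ZHistogram: binned vertical localization positions
#'
#' Histogram of z positions with uniform (default 1 nm) half-open bins
#' `[edge, edge + width)`, the substrate of the Gaussian layer fits.
#'
#' @slot binEdges strictly increasing numeric vector of uniform-width edges (nm).
#' @slot counts non-negative integer counts, one per bin.
#' @slot nTotal total count (sum of `counts`).
#' @slot roiLabel,protein provenance labels.
#' @export
setClass("ZHistogram",
  representation(binEdges = "numeric", counts = "integer", nTotal = "integer",
                 roiLabel = "character", protein = "character"))

setValidity("ZHistogram", function(object) {
  e <- object@binEdges
  if (length(e) < 2L) return("need at least one bin")
  w <- diff(e)
  if (any(w <= 0)) return("bin edges must be strictly increasing")
  if (max(abs(w - w[1])) > 1e-9 * w[1]) return("bins must have uniform width")
  if (length(object@counts) != length(e) - 1L)
    return("counts must have one entry per bin")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (sum(object@counts) != object@nTotal) return("sum(counts) must equal nTotal")
  TRUE
})

#' LayerFit: Gaussian decomposition of a z histogram
#'
#' Result of a 1- or 2-component Gaussian least-squares fit to a binned
#' vertical profile. Components are always stored in ascending `zCentre`
#' order ("low" before "high"); weights are the Gaussian areas normalized
#' to sum to 1.
#'
#' @slot modelOrder 1 or 2.
#' @slot zCentre,sVert,weight,amplitude per-component parameters (nm, nm,
#'   fraction, counts).
#' @slot rss residual sum of squares of the binned fit.
#' @slot bic least-squares BIC used for model selection.
#' @slot nTotal number of localizations behind the histogram.
#' @slot converged honest convergence flag from the optimizer.
#' @slot degenerate TRUE when the two components collapse
#'   (`|mu1 - mu2| < max(sigma)/2`).
#' @slot note diagnostic notes (e.g. low-count warning).
#' @export
setClass("LayerFit",
  representation(modelOrder = "integer", zCentre = "numeric", sVert = "numeric",
                 weight = "numeric", amplitude = "numeric", rss = "numeric",
                 bic = "numeric", nTotal = "integer", converged = "logical",
                 degenerate = "logical", note = "character"))

setValidity("LayerFit", function(object) {
  k <- object@modelOrder
  if (!k %in% c(1L, 2L)) return("modelOrder must be 1 or 2")
  if (length(object@zCentre) != k || length(object@sVert) != k ||
      length(object@weight) != k)
    return("zCentre, sVert, weight must have modelOrder entries")
  if (any(object@sVert <= 0)) return("sVert must be positive")
  if (is.unsorted(object@zCentre)) return("components must be ordered by ascending zCentre")
  if (abs(sum(object@weight) - 1) > 1e-6) return("weights must sum to 1")
  TRUE
})

#' ProteinSummary: layer statistics across ROIs
#'
#' Per-component combination of `LayerFit` results across regions of interest:
#' mean and SD of `Z_centre` and `s_vert`, plus the box-plot statistics used
#' for stratification summaries (median, quartiles, whiskers at
#' median +/- 1.5 x IQR).
#'
#' @slot protein label.
#' @slot modelOrder shared model order of the combined fits.
#' @slot stats data.frame, one row per component: `component`, `mean_z`,
#'   `sd_z`, `median_z`, `q1_z`, `q3_z`, `whisker_low`, `whisker_high`,
#'   `mean_svert`, `sd_svert`.
#' @slot nRois number of ROIs combined.
#' @export
setClass("ProteinSummary",
  representation(protein = "character", modelOrder = "integer",
                 stats = "data.frame", nRois = "integer"))

setValidity("ProteinSummary", function(object) {
  if (object@nRois < 1L) return("nRois must be >= 1")
  s <- object@stats
  if (nrow(s) != object@modelOrder) return("stats must have one row per component")
  if (any(s$q1_z > s$median_z | s$median_z > s$q3_z))
    return("quartiles must satisfy q1 <= median <= q3")
  TRUE
})

#' TagGeometry: vertical geometry of a two-ended molecule
#'
#' N-/C-terminal tag layer centres, their signed vertical separation
#' `deltaZ = z_c - z_n`, the orientation verdict, and (when the molecule's
#' full length is supplied) the inclination angle
#' `theta = asin(|deltaZ| / length)` in degrees.
#'
#' @slot protein label.
#' @slot zN,zC layer centres of the N- and C-terminal tags (nm).
#' @slot deltaZ signed separation `zC - zN` (nm); positive = C above N.
#' @slot length assumed full molecular length (nm), NA when not supplied.
#' @slot theta inclination angle (degrees), NA without a length.
#' @slot orientation `"C-above-N"`, `"N-above-C"` or `"level"` (within the
#'   resolution floor).
#' @slot resolutionFloor |deltaZ| at or below which the verdict is "level" (nm).
#' @export
setClass("TagGeometry",
  representation(protein = "character", zN = "numeric", zC = "numeric",
                 deltaZ = "numeric", length = "numeric", theta = "numeric",
                 orientation = "character", resolutionFloor = "numeric"))

setValidity("TagGeometry", function(object) {
  if (!object@orientation %in% c("C-above-N", "N-above-C", "level"))
    return("orientation must be C-above-N, N-above-C or level")
  if (!is.na(object@theta) && (object@theta < 0 || object@theta > 90))
    return("theta must lie in [0, 90] degrees")
  TRUE
})

#' LineProfile: normalized intensity along a segment
#'
#' Intensity averaged perpendicular to a segment over a stated width, sampled
#' at pixel pitch and divided by its maximum, so `max(values) == 1`.
#'
#' @slot positions distances along the segment (nm), monotone.
#' @slot values normalized intensities in `[0, 1]`.
#' @slot endpoints 2 x 2 matrix (rows = segment ends, columns = x, y in nm).
#' @slot width averaging width (nm).
#' @export
setClass("LineProfile",
  representation(positions = "numeric", values = "numeric",
                 endpoints = "matrix", width = "numeric"))

setValidity("LineProfile", function(object) {
  if (length(object@positions) != length(object@values))
    return("positions and values must have equal length")
  if (length(object@values) > 0) {
    if (is.unsorted(object@positions)) return("positions must be monotone")
    if (abs(max(object@values) - 1) > 1e-9) return("profile must be normalized to max 1")
  }
  TRUE
})

#' SurfaceFit: quadratic surface fit of a 3D point cloud
#'
#' Ordinary least squares of `z = c0 + c1 x + c2 y + c3 x^2 + c4 xy + c5 y^2`,
#' with principal curvatures taken as the eigenvalues of the quadratic-form
#' Hessian `[[2 c3, c4], [c4, 2 c5]]` (1/nm). A `flat` verdict is issued when
#' both |curvatures| fall below a configured threshold.
#'
#' @slot coefficients named numeric vector `c0`..`c5`.
#' @slot curvatures two eigenvalues (1/nm).
#' @slot flat flat-surface verdict.
#' @slot rss residual sum of squares.
#' @slot nPoints number of points fitted.
#' @export
setClass("SurfaceFit",
  representation(coefficients = "numeric", curvatures = "numeric",
                 flat = "logical", rss = "numeric", nPoints = "integer"))

setValidity("SurfaceFit", function(object) {
  if (length(object@coefficients) != 6L) return("need 6 coefficients c0..c5")
  if (object@nPoints < 6L) return("nPoints must be >= 6")
  if (any(is.na(object@curvatures))) return("curvatures must be real")
  TRUE
})

#' AdhesionMap: segmented adhesions in one image
#'
#' A labeled image plus one record per adhesion: area in square micrometres,
#' centroid, and (when colony edge/centre masks were supplied) the class.
#'
#' @slot labels integer label matrix (0 = background).
#' @slot table data.frame with columns `label`, `area_um2`, `x_px`, `y_px`,
#'   `klass` (`"edge"`, `"centre"` or NA).
#' @slot pixelUm micrometres per pixel.
#' @export
setClass("AdhesionMap",
  representation(labels = "matrix", table = "data.frame", pixelUm = "numeric"))

setValidity("AdhesionMap", function(object) {
  tab <- object@table
  if (object@pixelUm <= 0) return("pixelUm must be positive")
  if (nrow(tab) > 0) {
    if (anyDuplicated(tab$label)) return("labels must be unique")
    if (any(tab$label <= 0)) return("labels must be positive")
    if (any(tab$area_um2 <= 0)) return("areas must be positive")
  }
  present <- sort(unique(object@labels[object@labels > 0]))
  if (!identical(as.integer(present), as.integer(sort(tab$label))))
    return("label matrix and table must describe the same adhesions")
  TRUE
})

#' AreaMixtureFit: hyper-exponential adhesion-area model
#'
#' Maximum-likelihood fit (via EM) of the two-component exponential mixture
#' `w Exp(mean a1) + (1 - w) Exp(mean a2)` to raw adhesion areas, with the
#' identifiability convention `a1 < a2`. `a2` is the characteristic area of
#' the large-adhesion population.
#'
#' @slot a1,a2 characteristic areas (um^2), `a1 < a2`.
#' @slot w mixture weight of the `a1` component.
#' @slot se named standard errors (`w`, `a1`, `a2`) from the observed
#'   information; NA when the information matrix is singular.
#' @slot logLik final log-likelihood.
#' @slot n sample size.
#' @slot trace per-iteration log-likelihood of the best EM run.
#' @slot degenerate TRUE when the fit collapses to a single component.
#' @export
setClass("AreaMixtureFit",
  representation(a1 = "numeric", a2 = "numeric", w = "numeric", se = "numeric",
                 logLik = "numeric", n = "integer", trace = "numeric",
                 degenerate = "logical"))

setValidity("AreaMixtureFit", function(object) {
  if (object@a1 > object@a2) return("components must be ordered a1 <= a2")
  if (object@w < 0 || object@w > 1) return("w must lie in [0, 1]")
  TRUE
})

#' TrackSet: adhesion tracks through a movie
#'
#' Tracks built by frame-to-frame overlap linking of labeled adhesion images.
#' Frames of a track are contiguous (no gap closing).
#'
#' @slot tracks data.frame: `track_id`, `klass`, `birth_frame`, `death_frame`.
#' @slot frameAreas data.frame: `track_id`, `frame`, `area_um2`.
#' @slot frameIntervalMin minutes between frames.
#' @export
setClass("TrackSet",
  representation(tracks = "data.frame", frameAreas = "data.frame",
                 frameIntervalMin = "numeric"))

setValidity("TrackSet", function(object) {
  if (object@frameIntervalMin <= 0) return("frameIntervalMin must be positive")
  tr <- object@tracks
  if (nrow(tr) > 0 && any(tr$death_frame < tr$birth_frame))
    return("death_frame must be >= birth_frame")
  if (nrow(object@frameAreas) > 0 && any(object@frameAreas$area_um2 <= 0))
    return("per-frame areas must be positive")
  TRUE
})

#' LayerSpec: generative model of one protein's vertical layers
#'
#' Specification of a synthetic localization cloud: a 1- or 2-component
#' Gaussian vertical profile, a lateral geometry (uniform disc, edge ring,
#' cup, wall, or uniform annulus), and an optional uniform background
#' fraction.
#'
#' @slot protein label.
#' @slot components data.frame `z_centre`, `s_vert` (nm), `weight`
#'   (positive, summing to 1).
#' @slot lateral one of `uniform_disc`, `edge_ring`, `cup`, `wall`,
#'   `uniform_annulus`.
#' @slot lateralParams list: `radius_nm`, `rim_width_nm`, `cup_k`
#'   (nm added per nm^2 of squared radius), `wall_offset_nm`.
#' @slot count number of localizations to draw.
#' @slot backgroundFraction fraction drawn uniformly in z over
#'   `backgroundZRange` and uniformly in the lateral disc.
#' @slot backgroundZRange nm range of the background layer.
#' @export
setClass("LayerSpec",
  representation(protein = "character", components = "data.frame",
                 lateral = "character", lateralParams = "list",
                 count = "integer", backgroundFraction = "numeric",
                 backgroundZRange = "numeric"))

setValidity("LayerSpec", function(object) {
  cmp <- object@components
  if (nrow(cmp) < 1L) return("need at least one component")
  if (any(cmp$weight <= 0)) return("component weights must be positive")
  if (abs(sum(cmp$weight) - 1) > 1e-9) return("component weights must sum to 1")
  if (any(cmp$s_vert <= 0)) return("s_vert must be positive")
  if (object@count < 0L) return("count must be >= 0")
  bf <- object@backgroundFraction
  if (bf < 0 || bf >= 1) return("backgroundFraction must lie in [0, 1)")
  if (!object@lateral %in% c("uniform_disc", "edge_ring", "cup", "wall",
                             "uniform_annulus"))
    return("unknown lateral geometry")
  TRUE
})

#' ColonySpec: static layout of a synthetic colony
#'
#' @slot imageShape integer c(rows, cols) in pixels.
#' @slot pixelUm micrometres per pixel.
#' @slot colonyPolygon two-column matrix of vertices in pixel coordinates.
#' @slot edgeStripUm edge-strip thickness in micrometres.
#' @slot nEdgeFa,nCentreFa adhesion counts per class.
#' @slot areaModel list with elements `edge` and `centre`, each
#'   `list(a1, a2, w)` in um^2 (`a1 < a2`): the hyper-exponential model the
#'   maximal adhesion sizes are drawn from.
#' @export
setClass("ColonySpec",
  representation(imageShape = "integer", pixelUm = "numeric",
                 colonyPolygon = "matrix", edgeStripUm = "numeric",
                 nEdgeFa = "integer", nCentreFa = "integer",
                 areaModel = "list"))

setValidity("ColonySpec", function(object) {
  if (object@pixelUm <= 0) return("pixelUm must be positive")
  if (object@edgeStripUm <= 0) return("edgeStripUm must be positive")
  for (cls in c("edge", "centre")) {
    m <- object@areaModel[[cls]]
    if (is.null(m)) return("areaModel needs edge and centre entries")
    if (m$a1 >= m$a2) return("areaModel requires a1 < a2")
    if (m$w < 0 || m$w > 1) return("areaModel weight must lie in [0, 1]")
  }
  TRUE
})

#' MovieSpec: temporal rules of a synthetic colony movie
#'
#' Edge adhesions are stable: they appear at the first frame, grow
#' log-linearly to their maximal size and persist. Centre adhesions are
#' dynamic: they are born throughout the movie and disappear after an
#' exponentially distributed lifetime.
#'
#' @slot nFrames number of frames (>= 1).
#' @slot frameIntervalMin minutes per frame.
#' @slot centreLifetimeMeanMin mean exponential lifetime of centre
#'   adhesions (minutes).
#' @slot centreBirthRate expected centre-adhesion births per frame.
#' @slot growthFrames frames over which a new adhesion grows to maximal size.
#' @export
setClass("MovieSpec",
  representation(nFrames = "integer", frameIntervalMin = "numeric",
                 centreLifetimeMeanMin = "numeric", centreBirthRate = "numeric",
                 growthFrames = "integer"))

setValidity("MovieSpec", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (object@frameIntervalMin <= 0) return("frameIntervalMin must be positive")
  if (object@centreLifetimeMeanMin <= 0) return("centre lifetime mean must be positive")
  TRUE
})
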