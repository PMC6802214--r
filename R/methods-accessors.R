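# Accessor and show() methods for the package's S4 classes (generics in
# AllGenerics.R, classes in AllClasses.R).

## ---- accessors ----#' @rdname accessors
#' @export
setMethod("locData", "LocalizationTable", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("nLocalizations", "LocalizationTable", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setMethod("channelNames", "LocalizationTable", function(x) {
  if (nrow(x@records) == 0L) character(0) else sort(unique(x@records$channel))
})

#' @rdname accessors
#' @export
setMethod("zCentre", "LayerFit", function(x) x@zCentre)

#' @rdname accessors
#' @export
setMethod("sVert", "LayerFit", function(x) x@sVert)

#' @rdname accessors
#' @export
setMethod("componentWeights", "LayerFit", function(x) x@weight)

#' @rdname accessors
#' @export
setMethod("modelOrder", "LayerFit", function(x) x@modelOrder)

#' @rdname accessors
#' @export
setMethod("isConverged", "LayerFit", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("isDegenerate", "LayerFit", function(x) x@degenerate)

#' @rdname accessors
#' @export
setMethod("zCentre", "ProteinSummary", function(x) {
  stats::setNames(x@stats$mean_z, x@stats$component)
})

#' @rdname accessors
#' @export
setMethod("sVert", "ProteinSummary", function(x) {
  stats::setNames(x@stats$mean_svert, x@stats$component)
})

#' @rdname accessors
#' @export
setMethod("modelOrder", "ProteinSummary", function(x) x@modelOrder)

#' @rdname accessors
#' @export
setMethod("adhesionTable", "AdhesionMap", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("trackTable", "TrackSet", function(x) x@tracks)

## ---- show methods ----

setMethod("show", "LocalizationTable", function(object) {
  cat("LocalizationTable with", nrow(object@records), "localizations\n")
  ch <- channelNames(object)
  if (length(ch)) cat("  channels:", paste(ch, collapse = ", "), "\n")
  if (nrow(object@records)) {
    z <- object@records$z_nm
    cat(sprintf("  z range: %.1f .. %.1f nm\n", min(z), max(z)))
  }
})

setMethod("show", "RoiRegion", function(object) {
  cat(sprintf("RoiRegion '%s' (%s): %d vertices, area %.3g nm^2\n",
              object@label, object@klass, nrow(object@polygon),
              polygonArea(object@polygon[, 1], object@polygon[, 2])))
})

setMethod("show", "ZHistogram", function(object) {
  w <- diff(object@binEdges[1:2])
  cat(sprintf("ZHistogram: %d bins of %.3g nm, n = %d", length(object@counts),
              w, object@nTotal))
  if (nzchar(object@protein)) cat(", protein =", object@protein)
  cat("\n")
})

setMethod("show", "LayerFit", function(object) {
  cat(sprintf("LayerFit (%d component%s, n = %d)%s\n", object@modelOrder,
              if (object@modelOrder > 1L) "s" else "", object@nTotal,
              if (object@degenerate) " [degenerate]" else ""))
  for (i in seq_len(object@modelOrder)) {
    cat(sprintf("  Z_centre = %.1f nm, s_vert = %.1f nm, weight = %.2f\n",
                object@zCentre[i], object@sVert[i], object@weight[i]))
  }
})

setMethod("show", "ProteinSummary", function(object) {
  cat(sprintf("ProteinSummary '%s': %d component(s) over %d ROI(s)\n",
              object@protein, object@modelOrder, object@nRois))
  print(object@stats, row.names = FALSE, digits = 4)
})

setMethod("show", "TagGeometry", function(object) {
  cat(sprintf("TagGeometry '%s': z_N = %.1f nm, z_C = %.1f nm, delta_z = %+.1f nm (%s)\n",
              object@protein, object@zN, object@zC, object@deltaZ,
              object@orientation))
  if (!is.na(object@theta))
    cat(sprintf("  inclination theta = %.1f deg (length %.0f nm)\n",
                object@theta, object@length))
})

setMethod("show", "SurfaceFit", function(object) {
  cat(sprintf("SurfaceFit over %d points: curvatures %.3g, %.3g 1/nm%s\n",
              object@nPoints, object@curvatures[1], object@curvatures[2],
              if (object@flat) " [flat]" else ""))
})

setMethod("show", "AdhesionMap", function(object) {
  cat(sprintf("AdhesionMap: %d adhesions, pixel %.3g um\n",
              nrow(object@table), object@pixelUm))
})

setMethod("show", "AreaMixtureFit", function(object) {
  cat(sprintf(
    "AreaMixtureFit (n = %d): a1 = %.3g um^2, a2 = %.3g um^2, w = %.2f%s\n",
    object@n, object@a1, object@a2, object@w,
    if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d tracks at %.3g min/frame\n",
              nrow(object@tracks), object@frameIntervalMin))
})
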