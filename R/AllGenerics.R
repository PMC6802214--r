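#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes:
#' `locData()` returns the underlying localization data.frame,
#' `nLocalizations()` the number of records, `channelNames()` the set of
#' channel labels, `zCentre()`/`sVert()`/`componentWeights()` the fitted layer
#' parameters (in ascending `zCentre` order for two-component fits),
#' `modelOrder()` the number of Gaussian components, `isConverged()` and
#' `isDegenerate()` the fit diagnostics, and `adhesionTable()`/`trackTable()`
#' the per-adhesion and per-track record tables.
#'
#' @param x An object of the corresponding class.
#' @return The slot contents (see each method's class documentation).
#' @name accessors
#' @aliases locData nLocalizations channelNames zCentre sVert componentWeights
#'   modelOrder isConverged isDegenerate adhesionTable trackTable
#' @examples
#' tab <- LocalizationTable(data.frame(x_nm = 1, y_nm = 2, z_nm = 3,
#'                                     channel = "paxillin"))
#' nLocalizations(tab)
#' channelNames(tab)
NULL

#' @rdname accessors
#' @export
setGeneric("locData", function(x) standardGeneric("locData"))

#' @rdname accessors
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("zCentre", function(x) standardGeneric("zCentre"))

#' @rdname accessors
#' @export
setGeneric("sVert", function(x) standardGeneric("sVert"))

#' @rdname accessors
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))

#' @rdname accessors
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("adhesionTable", function(x) standardGeneric("adhesionTable"))

#' @rdname accessors
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))
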