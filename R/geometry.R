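# Tag-pair geometry for two-ended molecules (talin, vinculin): signed
# vertical separation of the N- and C-terminal tag layers, the orientation
# verdict, the inclination angle, and between-protein layer offsets.

.summaryMeanZ <- function(summary) {
  stopifnot(methods::is(summary, "ProteinSummary"))
  if (summary@modelOrder != 1L)
    stop("summaries must be single-component; got model order ",
         summary@modelOrder)
  summary@stats$mean_z[1]
}

#' Vertical separation and orientation of a tagged molecule
#'
#' `delta_z = Z_centre(C) - Z_centre(N)` using the mean combination statistic
#' of the two single-component summaries. Positive separation means the
#' C-terminus sits above the N-terminus ("C-above-N"); within the resolution
#' floor the verdict is "level". When the molecule's full length is supplied
#' the inclination angle `theta = asin(|delta_z| / length)` is computed.
#' The length is a required user input for theta: no literature constant is
#' assumed.
#'
#' @param summary_n,summary_c single-component [ProteinSummary-class]
#'   objects for the N- and C-terminal tags.
#' @param length optional full molecular length in nm.
#' @param protein label for the result.
#' @param resolution_floor |delta_z| (nm) at or below which the orientation
#'   is reported as "level" (default 5, motivated by the sub-20 nm
#'   instrument class).
#' @return A [TagGeometry-class].
#' @export
tagSeparation <- function(summary_n, summary_c, length = NA_real_,
                          protein = "", resolution_floor = 5) {
  zn <- .summaryMeanZ(summary_n)
  zc <- .summaryMeanZ(summary_c)
  dz <- zc - zn
  orientation <- if (abs(dz) <= resolution_floor) "level"
                 else if (dz > 0) "C-above-N" else "N-above-C"
  theta <- if (is.na(length)) NA_real_ else inclinationAngle(dz, length)
  if (protein == "" && nzchar(summary_n@protein)) protein <- summary_n@protein
  methods::new("TagGeometry", protein = protein, zN = zn, zC = zc,
               deltaZ = dz, length = as.numeric(length), theta = theta,
               orientation = orientation, resolutionFloor = resolution_floor)
}

#' Inclination angle of an extended molecule
#'
#' `theta = asin(|delta_z| / length)` in degrees: the tilt a molecule of the
#' given full length must have for its two ends to sit `delta_z` apart
#' vertically.
#'
#' @param delta_z signed vertical tag separation (nm).
#' @param length full molecular length (nm, > 0).
#' @return Angle in degrees, in `[0, 90]`.
#' @examples
#' inclinationAngle(15, 30)  # 30 degrees
#' @export
inclinationAngle <- function(delta_z, length) {
  if (length <= 0) stop("length must be positive")
  if (abs(delta_z) > length)
    stop("impossible configuration: |delta_z| exceeds the molecular length")
  asin(abs(delta_z) / length) * 180 / pi
}

#' Vertical offset between two protein layers
#'
#' `Z_centre(a) - Z_centre(b)` from two single-component summaries;
#' anti-symmetric in its arguments.
#'
#' @param summary_a,summary_b single-component [ProteinSummary-class]
#'   objects.
#' @return Signed offset in nm.
#' @export
layerOffset <- function(summary_a, summary_b) {
  .summaryMeanZ(summary_a) - .summaryMeanZ(summary_b)
}
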