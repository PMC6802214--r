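# Adhesion dynamics: frame-to-frame overlap tracking of labeled adhesion
# images and the derived read-outs — lifetime and maximal-size frequency
# distributions per colony class and per-frame coverage fractions.

.stackFromInput <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    return(list(stack = frames, maps = NULL))
  if (is.list(frames) && all(vapply(frames, methods::is, logical(1), "AdhesionMap"))) {
    stack <- array(0L, dim = c(dim(frames[[1]]@labels), length(frames)))
    for (f in seq_along(frames)) {
      if (!identical(dim(frames[[f]]@labels), dim(frames[[1]]@labels)))
        stop("mismatched frame shapes")
      stack[, , f] <- frames[[f]]@labels
    }
    return(list(stack = stack, maps = frames))
  }
  stop("frames must be a rows x cols x frames array or a list of AdhesionMap")
}

#' Track adhesions through a labeled movie
#'
#' Links regions frame to frame by maximal pixel overlap: a region with no
#' overlap starts a new track; a track with no successor ends (no gap
#' closing — a one-frame disappearance ends the track). Ties are broken by
#' larger overlap area then smaller region label; when a track splits, the
#' largest fragment keeps the identity. Track frames are therefore
#' contiguous.
#'
#' @param frames integer label array (rows x cols x frames, per-frame labels
#'   need not be consistent across frames) or a list of
#'   [AdhesionMap-class] objects sharing geometry.
#' @param pixel_um micrometres per pixel (taken from the maps when given).
#' @param frame_interval_min minutes between frames.
#' @param edge_mask,centre_mask optional logical matrices; each track is
#'   classified by majority overlap of its birth region (ties to edge).
#' @return A [TrackSet-class].
#' @export
trackAdhesions <- function(frames, pixel_um = NULL, frame_interval_min = 1,
                           edge_mask = NULL, centre_mask = NULL) {
  inp <- .stackFromInput(frames)
  stack <- inp$stack
  if (is.null(pixel_um)) {
    if (!is.null(inp$maps)) pixel_um <- inp$maps[[1]]@pixelUm
    else stop("pixel_um is required with an array input")
  }
  nF <- dim(stack)[3]
  nextId <- 1L
  recs <- list()
  trackKlass <- character(0)
  prevTrackImg <- NULL
  for (f in seq_len(nF)) {
    lab <- stack[, , f]
    labs <- sort(unique(lab[lab > 0L]))
    assign <- stats::setNames(rep(NA_integer_, length(labs)), labs)
    if (f > 1L && length(labs)) {
      both <- lab > 0L & prevTrackImg > 0L
      if (any(both)) {
        ov <- stats::aggregate(
          list(npix = rep(1L, sum(both))),
          by = list(track = prevTrackImg[both], lab = lab[both]), FUN = sum)
        ov <- ov[order(-ov$npix, ov$lab, ov$track), , drop = FALSE]
        usedTrack <- integer(0); usedLab <- integer(0)
        for (i in seq_len(nrow(ov))) {
          tk <- ov$track[i]; lb <- ov$lab[i]
          if (tk %in% usedTrack || lb %in% usedLab) next
          assign[as.character(lb)] <- tk
          usedTrack <- c(usedTrack, tk); usedLab <- c(usedLab, lb)
        }
      }
    }
    for (lb in labs) {
      if (is.na(assign[as.character(lb)])) {
        assign[as.character(lb)] <- nextId
        pix <- which(lab == lb)
        kl <- NA_character_
        if (!is.null(inp$maps)) {
          tab <- inp$maps[[f]]@table
          kl <- tab$klass[match(lb, tab$label)]
        } else if (!is.null(edge_mask) && !is.null(centre_mask)) {
          ne <- sum(edge_mask[pix]); ncn <- sum(centre_mask[pix])
          if (ne + ncn > 0) kl <- if (ne >= ncn) "edge" else "centre"
        }
        trackKlass[nextId] <- kl
        nextId <- nextId + 1L
      }
    }
    npix <- tabulate(lab[lab > 0L], nbins = max(lab, 1L))
    for (lb in labs) {
      recs[[length(recs) + 1L]] <- data.frame(
        track_id = assign[as.character(lb)], frame = f,
        area_um2 = npix[lb] * pixel_um^2)
    }
    trackImg <- matrix(0L, nrow(lab), ncol(lab))
    if (length(labs)) {
      pos <- lab > 0L
      trackImg[pos] <- assign[as.character(lab[pos])]
    }
    prevTrackImg <- trackImg
  }
  fa <- if (length(recs)) do.call(rbind, recs) else
    data.frame(track_id = integer(0), frame = integer(0), area_um2 = numeric(0))
  rownames(fa) <- NULL
  ids <- sort(unique(fa$track_id))
  tracks <- data.frame(
    track_id = ids,
    klass = if (length(trackKlass)) trackKlass[ids] else rep(NA_character_, length(ids)),
    birth_frame = vapply(ids, function(i) min(fa$frame[fa$track_id == i]), numeric(1)),
    death_frame = vapply(ids, function(i) max(fa$frame[fa$track_id == i]), numeric(1)),
    stringsAsFactors = FALSE)
  methods::new("TrackSet", tracks = tracks, frameAreas = fa,
               frameIntervalMin = frame_interval_min)
}

.binnedFrequency <- function(values, klass, bin_width, cap = NULL) {
  if (length(values) == 0L)
    return(data.frame(klass = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), freq = numeric(0)))
  if (!is.null(cap)) values <- pmin(values, cap)
  top <- if (!is.null(cap)) cap else max(values)
  nbins <- max(1L, ceiling(top / bin_width))
  idx <- pmin(floor(values / bin_width), nbins - 1L) + 1L
  out <- lapply(unique(klass[!is.na(klass)]), function(kl) {
    sel <- which(klass == kl)
    cnt <- tabulate(idx[sel], nbins = nbins)
    data.frame(klass = kl, bin_lo = (seq_len(nbins) - 1L) * bin_width,
               bin_hi = seq_len(nbins) * bin_width, freq = cnt / sum(cnt))
  })
  do.call(rbind, out)
}

#' Lifetime frequency distribution per colony class
#'
#' Lifetime = frames present x frame interval, capped at `cap_min`
#' (default 105 minutes, the shortest-replicate convention), then binned per
#' class and normalized so each class's frequencies sum to 1.
#'
#' @param tracks a [TrackSet-class].
#' @param cap_min lifetime cap in minutes (> 0).
#' @param bin_width bin width in minutes (default 15).
#' @return data.frame `klass`, `bin_lo`, `bin_hi`, `freq`; empty for an
#'   empty track set.
#' @export
lifetimeDistribution <- function(tracks, cap_min = 105, bin_width = 15) {
  stopifnot(methods::is(tracks, "TrackSet"))
  if (cap_min <= 0) stop("cap_min must be positive")
  tr <- tracks@tracks
  life <- (tr$death_frame - tr$birth_frame + 1) * tracks@frameIntervalMin
  .binnedFrequency(life, tr$klass, bin_width, cap = cap_min)
}

#' Maximal-size frequency distribution per colony class
#'
#' Each track's maximal area over its life, binned per class (default
#' 0.5 um^2 bins) and normalized per class.
#'
#' @param tracks a [TrackSet-class].
#' @param bin_um2 bin width in um^2.
#' @return data.frame `klass`, `bin_lo`, `bin_hi`, `freq`.
#' @export
maxSizeDistribution <- function(tracks, bin_um2 = 0.5) {
  stopifnot(methods::is(tracks, "TrackSet"))
  tr <- tracks@tracks
  if (nrow(tr) == 0L) return(.binnedFrequency(numeric(0), character(0), bin_um2))
  fa <- tracks@frameAreas
  mx <- vapply(tr$track_id, function(i) max(fa$area_um2[fa$track_id == i]),
               numeric(1))
  .binnedFrequency(mx, tr$klass, bin_um2)
}

#' Per-frame adhesion coverage per colony class
#'
#' For each frame, `100 x (adhesion pixels in class mask) / (class mask
#' pixels)`: the percentage of the edge strip and of the colony centre
#' covered by adhesions.
#'
#' @param stack integer label array rows x cols x frames.
#' @param edge_mask,centre_mask disjoint logical matrices.
#' @return data.frame `frame`, `edge_pct`, `centre_pct`; a class with an
#'   empty mask yields NA for that column with a warning.
#' @export
coverageFraction <- function(stack, edge_mask, centre_mask) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (any(edge_mask & centre_mask)) stop("edge and centre masks must be disjoint")
  ne <- sum(edge_mask); ncn <- sum(centre_mask)
  if (ne == 0L) warning("edge mask is empty: edge coverage undefined")
  if (ncn == 0L) warning("centre mask is empty: centre coverage undefined")
  nF <- dim(stack)[3]
  edge <- centre <- rep(NA_real_, nF)
  for (f in seq_len(nF)) {
    fg <- stack[, , f] > 0L
    if (ne > 0L) edge[f] <- 100 * sum(fg & edge_mask) / ne
    if (ncn > 0L) centre[f] <- 100 * sum(fg & centre_mask) / ncn
  }
  data.frame(frame = seq_len(nF), edge_pct = edge, centre_pct = centre)
}
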