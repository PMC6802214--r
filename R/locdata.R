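# Localization-table and ROI I/O: the substrate of every analysis stage.
# Canonical CSV dialect: comma separator, dot decimal, mandatory header,
# columns id,frame,x_nm,y_nm,z_nm,channel,precision_nm. A dialect mapping
# lets other localization-table exports (e.g. ThunderSTORM-style column
# names) be ingested.

#' Construct a LocalizationTable
#'
#' @param records data.frame with at least `x_nm`, `y_nm`, `z_nm`. Missing
#'   `id` is assigned sequentially, missing `frame` defaults to 0, missing
#'   `channel` to `"unknown"`, missing `precision_nm` to NA.
#' @param meta optional list of free-form metadata.
#' @return A [LocalizationTable-class] object.
#' @examples
#' LocalizationTable(data.frame(x_nm = c(1, 2), y_nm = 0, z_nm = c(50, 60),
#'                              channel = "paxillin"))
#' @export
LocalizationTable <- function(records = data.frame(), meta = list()) {
  if (nrow(records) > 0L) {
    needed <- c("x_nm", "y_nm", "z_nm")
    missing <- setdiff(needed, names(records))
    if (length(missing))
      stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
    if (is.null(records$id)) records$id <- seq_len(nrow(records))
    if (is.null(records$frame)) records$frame <- 0L
    if (is.null(records$channel)) records$channel <- "unknown"
    if (is.null(records$precision_nm)) records$precision_nm <- NA_real_
    records$id <- as.integer(records$id)
    records$frame <- as.integer(records$frame)
    records$channel <- as.character(records$channel)
    records <- records[, LOC_COLUMNS]
    rownames(records) <- NULL
  }
  methods::new("LocalizationTable", records = records, meta = meta)
}

#' Construct a polygonal region of interest
#'
#' @param label region label.
#' @param polygon n x 2 matrix (or coercible) of vertices in nm; must be a
#'   simple polygon with positive area. Do not repeat the first vertex.
#' @param klass region class; one of `fa`, `fa_adjacent`, `fa_distal`,
#'   `colony_edge`, `colony_centre`, `other`.
#' @return A [RoiRegion-class] object.
#' @examples
#' RoiRegion("fa1", cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)), "fa")
#' @export
RoiRegion <- function(label, polygon, klass = "fa") {
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  methods::new("RoiRegion", label = as.character(label), polygon = polygon,
               klass = klass)
}

#' Read a localization table from CSV
#'
#' Reads the canonical dialect (`id,frame,x_nm,y_nm,z_nm,channel,precision_nm`)
#' or, via `dialect`, any headered CSV whose columns can be mapped onto it.
#' Units are taken as nanometres. Ids are assigned sequentially when absent.
#'
#' @param path CSV file path.
#' @param dialect named character vector mapping canonical names to the
#'   file's column names, e.g. `c(x_nm = "x [nm]", y_nm = "y [nm]",
#'   z_nm = "z [nm]")`. Unmapped canonical columns are looked up by their
#'   own names.
#' @return A [LocalizationTable-class].
#' @examples
#' tab <- simulateLocalizations(LayerSpec("paxillin", 55.7, 8.5, count = 10), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeLocalizations(tab, f)
#' readLocalizations(f)
#' @export
readLocalizations <- function(path, dialect = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pick <- function(canon) {
    src <- if (canon %in% names(dialect)) dialect[[canon]] else canon
    if (src %in% names(raw)) raw[[src]] else NULL
  }
  if (nrow(raw) == 0L) return(LocalizationTable(meta = list(source = path)))
  rec <- list()
  for (canon in c("x_nm", "y_nm", "z_nm")) {
    v <- pick(canon)
    if (is.null(v)) stop("missing mandatory column: ", canon)
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v) & v != "")
    if (length(bad))
      stop("non-numeric value in column '", canon, "' at data row ", bad[1])
    rec[[canon]] <- vn
  }
  for (canon in c("id", "frame", "precision_nm")) {
    v <- pick(canon)
    if (!is.null(v)) rec[[canon]] <- suppressWarnings(as.numeric(v))
  }
  ch <- pick("channel")
  if (!is.null(ch)) rec$channel <- as.character(ch)
  LocalizationTable(as.data.frame(rec, stringsAsFactors = FALSE),
                    meta = list(source = path))
}

#' Write a localization table to canonical CSV
#'
#' Canonical header `id,frame,x_nm,y_nm,z_nm,channel,precision_nm`; missing
#' precision is written as an empty field. `writeLocalizations` followed by
#' [readLocalizations()] is the identity on valid tables.
#'
#' @param table a [LocalizationTable-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeLocalizations <- function(table, path) {
  stopifnot(methods::is(table, "LocalizationTable"))
  rec <- table@records
  if (nrow(rec) == 0L) rec <- stats::setNames(
    as.data.frame(matrix(nrow = 0, ncol = length(LOC_COLUMNS))), LOC_COLUMNS)
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write ROI definitions (JSON)
#'
#' ROI files are JSON arrays of objects
#' `{label, klass, polygon: [[x, y], ...]}` with coordinates in nm.
#'
#' @param path JSON file path.
#' @return `readRois` returns a list of [RoiRegion-class]; `writeRois`
#'   invisibly returns `path`.
#' @export
readRois <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  lapply(arr, function(o) {
    pg <- do.call(rbind, lapply(o$polygon, as.numeric))
    RoiRegion(o$label, pg, o$klass %||% "other")
  })
}

#' @rdname readRois
#' @param rois list of [RoiRegion-class] objects.
#' @export
writeRois <- function(rois, path) {
  arr <- lapply(rois, function(r) {
    list(label = r@label, klass = r@klass,
         polygon = lapply(seq_len(nrow(r@polygon)),
                          function(i) as.numeric(r@polygon[i, ])))
  })
  jsonlite::write_json(arr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select localizations inside a region of interest
#'
#' Retains records whose lateral position lies inside the ROI polygon; points
#' exactly on the boundary are included. Optionally restricts to one channel.
#' Record order is preserved, so the operation is idempotent and commutes
#' with channel filtering.
#'
#' @param table a [LocalizationTable-class].
#' @param roi a [RoiRegion-class].
#' @param channel optional channel label; must exist in the table.
#' @return The filtered [LocalizationTable-class].
#' @export
selectRoi <- function(table, roi, channel = NULL) {
  stopifnot(methods::is(table, "LocalizationTable"), methods::is(roi, "RoiRegion"))
  rec <- table@records
  if (!is.null(channel)) {
    if (!channel %in% rec$channel)
      stop("unknown channel label: ", channel)
    rec <- rec[rec$channel == channel, , drop = FALSE]
  }
  if (nrow(rec) > 0L) {
    keep <- pointsInPolygon(rec$x_nm, rec$y_nm,
                            roi@polygon[, 1], roi@polygon[, 2])
    rec <- rec[keep, , drop = FALSE]
  }
  rownames(rec) <- NULL
  methods::new("LocalizationTable", records = rec,
               meta = c(table@meta, list(roi = roi@label)))
}

#' Rasterize localizations into a 2D count image
#'
#' Pixel `(i, j)` (row i, column j) covers the half-open square
#' `[x0 + (j-1) p, x0 + j p) x [y0 + (i-1) p, y0 + i p)` with y increasing
#' downward, so every in-bounds localization lands in exactly one pixel and
#' the image total equals the number of in-bounds localizations.
#'
#' @param table a [LocalizationTable-class].
#' @param pixel_nm pixel size in nm (> 0).
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)` in nm.
#' @return Integer count matrix with attributes `pixel_nm` and `bounds`.
#' @export
renderDensity <- function(table, pixel_nm, bounds) {
  stopifnot(methods::is(table, "LocalizationTable"))
  if (!is.numeric(pixel_nm) || pixel_nm <= 0) stop("pixel_nm must be > 0")
  if (length(bounds) != 4L || bounds[2] <= bounds[1] || bounds[4] <= bounds[3])
    stop("degenerate bounds; need c(xmin, xmax, ymin, ymax) with positive extent")
  nx <- ceiling((bounds[2] - bounds[1]) / pixel_nm)
  ny <- ceiling((bounds[4] - bounds[3]) / pixel_nm)
  img <- matrix(0L, nrow = ny, ncol = nx)
  rec <- table@records
  if (nrow(rec) > 0L) {
    jx <- floor((rec$x_nm - bounds[1]) / pixel_nm) + 1L
    iy <- floor((rec$y_nm - bounds[3]) / pixel_nm) + 1L
    ok <- jx >= 1L & jx <= nx & iy >= 1L & iy <= ny
    if (any(ok)) {
      tab <- table(factor(iy[ok], levels = seq_len(ny)),
                   factor(jx[ok], levels = seq_len(nx)))
      img <- matrix(as.integer(tab), nrow = ny, ncol = nx)
    }
  }
  attr(img, "pixel_nm") <- pixel_nm
  attr(img, "bounds") <- bounds
  img
}
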