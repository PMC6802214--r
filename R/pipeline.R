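# Pipeline layer: schema-checked run configurations, stage execution and
# provenance manifests. A thin command-line wrapper over these functions is
# installed at inst/scripts/strata.R; every stage is equally usable as a
# plain function call.

.STAGE_SCHEMA <- list(
  simulate = list(required = c("protein", "seed"),
                  defaults = list(count = 20000L, lateral = "uniform_disc",
                                  background_fraction = 0, out_dir = ".")),
  zprofile = list(required = c("loc"),
                  defaults = list(bin_width = 1, model = "auto",
                                  channel = NULL, roi = NULL,
                                  out_dir = ".")),
  areas    = list(required = c("areas_csv"),
                  defaults = list(out_dir = "."))
)

#' Read a pipeline run configuration
#'
#' Configurations are YAML or JSON mappings with a `stage` field naming the
#' pipeline stage (`simulate`, `zprofile` or `areas`) plus that stage's
#' inputs and tunables. Fields left out fall back to recorded defaults; the
#' manifest written by [runStage()] echoes every effective value.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return Named list (the config).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg) || is.null(cfg$stage))
    stop("usage error: config must be a mapping with a 'stage' field")
  cfg
}

.checkConfig <- function(config) {
  stage <- config$stage
  if (is.null(stage) || !stage %in% names(.STAGE_SCHEMA))
    stop("usage error: stage must be one of ",
         paste(names(.STAGE_SCHEMA), collapse = ", "))
  sch <- .STAGE_SCHEMA[[stage]]
  missing <- setdiff(sch$required, names(config))
  if (length(missing))
    stop("usage error: stage '", stage, "' requires field(s): ",
         paste(missing, collapse = ", "))
  for (nm in names(sch$defaults))
    if (is.null(config[[nm]])) config[nm] <- sch$defaults[nm]
  config
}

.writeManifest <- function(config, inputs, outputs, dir) {
  manifest <- list(
    tool = "nanoFA",
    version = as.character(utils::packageVersion("nanoFA")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

.layerFitJSON <- function(fit) {
  list(model_order = modelOrder(fit), z_centre = zCentre(fit),
       s_vert = sVert(fit), weight = componentWeights(fit),
       rss = fit@rss, bic = fit@bic, n_total = fit@nTotal,
       converged = isConverged(fit), degenerate = isDegenerate(fit))
}

#' Execute one pipeline stage
#'
#' Validates the configuration against the stage schema, runs the stage,
#' writes its results under `config$out_dir` and emits a `manifest.json`
#' recording the tool version, the full effective configuration (seeds and
#' tunables included), MD5 hashes of the inputs and the output file names —
#' enough to regenerate any result file exactly.
#'
#' Stages: `simulate` draws a localization table at a protein's reference
#' layer parameters (or explicit `z_centre`/`s_vert` vectors) and writes the
#' canonical CSV; `zprofile` bins a localization CSV (optionally one ROI /
#' channel) and fits Gaussian layers with `model` = `"auto"`, `1` or `2`;
#' `areas` fits the hyper-exponential model to a one-column CSV of areas.
#'
#' @param config named list, e.g. from [readRunConfig()].
#' @return Invisibly, a list with `outputs` (paths) and `manifest` (path).
#' @export
runStage <- function(config) {
  config <- .checkConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  outputs <- character(0)
  if (config$stage == "simulate") {
    spec <- if (!is.null(config$z_centre))
      LayerSpec(config$protein, config$z_centre, config$s_vert,
                config$weight %||% NULL, lateral = config$lateral,
                count = config$count,
                background_fraction = config$background_fraction)
    else referenceLayerSpec(config$protein, count = config$count,
                            lateral = config$lateral,
                            background_fraction = config$background_fraction)
    tab <- simulateLocalizations(spec, seed = config$seed)
    out <- file.path(config$out_dir, paste0(config$protein, "_loc.csv"))
    writeLocalizations(tab, out)
    outputs <- out
  } else if (config$stage == "zprofile") {
    inputs <- config$loc
    tab <- readLocalizations(config$loc)
    if (!is.null(config$roi)) {
      inputs <- c(inputs, config$roi)
      rois <- readRois(config$roi)
      labels <- vapply(rois, function(r) r@label, character(1))
      roi <- if (!is.null(config$roi_label))
        rois[[match(config$roi_label, labels)]] else rois[[1]]
      tab <- selectRoi(tab, roi, channel = config$channel)
    }
    hist <- zHistogram(tab, bin_width = config$bin_width,
                       channel = if (is.null(config$roi)) config$channel else NULL)
    res <- if (identical(config$model, "auto")) {
      sel <- selectLayerModel(hist)
      list(model_selected = sel$modelOrder,
           fit1 = .layerFitJSON(sel$fit1),
           fit2 = if (!is.null(sel$fit2)) .layerFitJSON(sel$fit2))
    } else if (config$model %in% c(1, "1")) {
      list(model_selected = 1L, fit1 = .layerFitJSON(fitGaussianLayer(hist)))
    } else if (config$model %in% c(2, "2")) {
      list(model_selected = 2L, fit2 = .layerFitJSON(fitTwoGaussianLayers(hist)))
    } else stop("usage error: model must be auto, 1 or 2")
    out <- file.path(config$out_dir, "fits.json")
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         null = "null")
    outputs <- out
  } else if (config$stage == "areas") {
    inputs <- config$areas_csv
    areas <- utils::read.csv(config$areas_csv)[[1]]
    fit <- fitAreaMixture(areas)
    out <- file.path(config$out_dir, "areas.json")
    jsonlite::write_json(
      list(a1 = fit@a1, a2 = fit@a2, w = fit@w, log_lik = fit@logLik,
           n = fit@n, degenerate = fit@degenerate,
           se = as.list(fit@se)),
      out, auto_unbox = TRUE, digits = NA)
    outputs <- out
  }
  manifest <- .writeManifest(config, inputs, outputs, config$out_dir)
  invisible(list(outputs = outputs, manifest = manifest))
}
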