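## End-to-end orchestration: segregation features -> VIF screen ->
## models 1-4 -> DIC comparison -> exceedance classification, with
## delimited-text outputs and a machine-readable run manifest.

#' Read an area table from delimited text
#'
#' Expects one row per area with at least `areaId`, `storeCount` and
#' `population` columns; any covariate columns come along. Rows are
#' returned sorted by `areaId` (the package's canonical order).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readAreaTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("areaId", "storeCount", "population")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop(path, " lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$areaId)) stop("duplicate areaId values in ", path)
  if (any(tab$storeCount < 0) || any(tab$storeCount != floor(tab$storeCount))) {
    stop("storeCount must be nonnegative integers (", path, ")")
  }
  if (any(tab$population <= 0)) stop("population must be positive (", path, ")")
  tab[order(tab$areaId), , drop = FALSE]
}

#' Run the full spatial analysis pipeline
#'
#' Computes segregation features (when a composition table is supplied),
#' screens the full covariate set with the VIF, fits the requested nested
#' models by MCMC, compares them by DIC, classifies exceedance
#' probabilities per model, and writes every table as delimited text plus
#' a JSON run manifest. A VIF at or above the threshold produces a warning
#' but does not stop the run (screen-then-proceed). Identical inputs and
#' seed reproduce byte-identical output tables.
#'
#' @param areaTable data.frame (or CSV path) with `areaId`, `storeCount`,
#'   `population` and covariate columns; rows are aligned to the graph by
#'   sorted `areaId`.
#' @param graph an [AreaGraph-class] (or path to an edge-list CSV /
#'   GeoJSON file, dispatched on extension).
#' @param outDir output directory, created if needed.
#' @param composition optional data.frame (or CSV path) with `white`,
#'   `black`, `asian`, `hispanic` shares and `population`; when given, the
#'   segregation feature block is (re)computed from it.
#' @param models integer subset of 1:4 to fit.
#' @param priors,settings,seed passed to [fitMcmc()].
#' @param exceedanceCuts hotspot/coldspot cut-points, see
#'   [classifyExceedance()].
#' @param vifThreshold collinearity flag level.
#' @param writeDraws also write the retained draws of each fit as a
#'   draws_model<k>.csv column archive (off by default; they are large).
#' @return invisibly, a list with the in-memory results: `features`, `vif`,
#'   `fits`, `summaries`, `comparison`, `exceedance`, `manifest`.
#' @export
runPipeline <- function(areaTable, graph, outDir,
                        composition = NULL,
                        models = 1:4,
                        priors = defaultPriors(),
                        settings = samplerSettings(),
                        seed = 1L,
                        exceedanceCuts = c(0.2, 0.8),
                        vifThreshold = 6,
                        writeDraws = FALSE) {
  t0 <- Sys.time()
  if (is.character(areaTable)) areaTable <- readAreaTable(areaTable)
  if (is.character(graph)) {
    graph <- if (grepl("\\.(geojson|json)$", graph, ignore.case = TRUE)) {
      areaGraphFromGeoJSON(graph)
    } else {
      readEdgeList(graph)
    }
  }
  if (is.character(composition)) composition <- read.csv(composition)
  areaTable <- areaTable[order(areaTable$areaId), , drop = FALSE]
  if (!identical(as.character(areaTable$areaId), areaIds(graph))) {
    stop("areaTable ids do not match the graph's areas")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # segregation features
  features <- NULL
  if (!is.null(composition)) {
    composition <- composition[order(composition$areaId), , drop = FALSE]
    features <- segregationFeatures(
      composition[, c("white", "black", "asian", "hispanic")], graph,
      population = composition$population)
    for (nm in setdiff(names(features), "areaId")) areaTable[[nm]] <- features[[nm]]
    emit(features, "segregation_features.csv")
  }

  # VIF screen on the full-model covariate set
  spec4 <- modelSpec(4L)
  have <- intersect(spec4$covariates, names(areaTable))
  vif <- NULL
  if (length(have) >= 2L) {
    X4 <- designMatrix(areaTable, modifyList(spec4, list(covariates = have)))
    vif <- computeVif(X4, threshold = vifThreshold)
    if (any(vif$flagged)) {
      warning("VIF >= ", vifThreshold, " for: ",
              paste(vif$covariate[vif$flagged], collapse = ", "),
              " (proceeding)")
    }
    emit(vif, "vif.csv")
  }

  # fit the nested models
  fits <- list(); summaries <- list(); dics <- list(); exceed <- list()
  for (m in models) {
    spec <- modelSpec(m)
    spec$covariates <- intersect(spec$covariates, names(areaTable))
    fit <- fitMcmc(areaTable, graph, spec, priors = priors,
                   settings = settings, seed = seed + 101L * m)
    fits[[paste0("model", m)]] <- fit
    s <- summarizePosterior(fit)
    summaries[[paste0("model", m)]] <- s
    emit(s$coefficients, sprintf("fit_model%d.csv", m))
    emit(s$hyper, sprintf("hyper_model%d.csv", m))
    dics[[paste0("model", m)]] <- dic(fit, areaTable, spec)
    ex <- exceedanceProbability(fit)
    ex$class <- classifyExceedance(ex$exceedanceProb, cuts = exceedanceCuts)
    exceed[[paste0("model", m)]] <- ex
    emit(ex, sprintf("exceedance_model%d.csv", m))
    if (writeDraws) {
      draws <- cbind(as.data.frame(betaDraws(fit)), hyperDraws(fit))
      emit(draws, sprintf("draws_model%d.csv", m))
    }
  }

  comparison <- NULL
  if (length(dics) >= 2L) {
    comparison <- compareModels(dics)
    emit(comparison, "comparison.csv")
  }

  manifest <- list(
    package = "zipbym",
    version = as.character(packageVersion("zipbym")),
    seed = as.integer(seed),
    models = as.integer(models),
    nAreas = nAreas(graph),
    connected = isConnected(graph),
    sampler = unclass(settings),
    priors = unclass(priors),
    exceedanceCuts = exceedanceCuts,
    vifThreshold = vifThreshold,
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs)),
    wallTimeSec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(features = features, vif = vif, fits = fits,
                 summaries = summaries, comparison = comparison,
                 exceedance = exceed, dics = dics, manifest = manifest))
}

#' Run the pipeline from a YAML configuration file
#'
#' The file names the inputs and settings:
#' ```yaml
#' area_table: path/to/area_table.csv
#' adjacency: path/to/edges.csv        # or a .geojson polygon layer
#' composition: path/to/composition.csv   # optional
#' out_dir: path/to/run
#' seed: 1
#' models: [1, 2, 3, 4]
#' sampler: {n_iter: 20000, n_burn: 10000, n_chains: 4, thin: 1}
#' exceedance_cuts: [0.2, 0.8]
#' ```
#'
#' @param path YAML file path.
#' @return see [runPipeline()].
#' @export
runPipelineFromConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("area_table", "adjacency", "out_dir")) {
    if (is.null(cfg[[nm]])) stop("config lacks required field '", nm, "'")
  }
  for (nm in c("area_table", "adjacency", "composition")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop("config file '", nm, "' does not exist: ", cfg[[nm]])
    }
  }
  s <- cfg$sampler
  settings <- if (is.null(s)) samplerSettings() else
    samplerSettings(nIter = s$n_iter %||% 20000L,
                    nBurn = s$n_burn %||% 10000L,
                    nChains = s$n_chains %||% 4L,
                    thin = s$thin %||% 1L)
  runPipeline(
    areaTable = cfg$area_table,
    graph = cfg$adjacency,
    outDir = cfg$out_dir,
    composition = cfg$composition,
    models = if (is.null(cfg$models)) 1:4 else as.integer(unlist(cfg$models)),
    settings = settings,
    seed = as.integer(cfg$seed %||% 1L),
    exceedanceCuts = if (is.null(cfg$exceedance_cuts)) c(0.2, 0.8) else
      as.numeric(unlist(cfg$exceedance_cuts)),
    vifThreshold = cfg$vif_threshold %||% 6,
    writeDraws = isTRUE(cfg$write_draws)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
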