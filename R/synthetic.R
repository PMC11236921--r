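## Synthetic tract-lattice generator: the study conditions the package is
## validated under. A ~96-tract contiguous lattice with spatially
## autocorrelated racial composition, SES covariates correlated with the
## Black share, and ZIP-BYM-generated store counts.

#' Simulation configuration
#'
#' Defaults emulate a mid-size, strongly segregated US city observed at
#' census-tract scale: a 12 x 8 lattice (96 tracts), contiguous
#' Black-majority and White-majority regions produced by a smoothed
#' polarisation field, five SES covariates correlated with the Black share
#' at Table-1-like percentage scales, and counts generated from the
#' ZIP-BYM law with a segregation-only truth (all SES effects zero).
#' True effect directions follow the study narrative (fewer stores with
#' segregation and Black clustering, more with White clustering); the
#' magnitudes are moderate values chosen to be detectable at n ~ 100.
#'
#' @param nx,ny lattice dimensions (areas = nx * ny, each >= 2).
#' @param baseline softmax intercepts per racial group; the defaults give
#'   citywide shares of roughly 40/49/2/9 percent
#'   (White/Black/Asian/Hispanic).
#' @param polarization strength of the White-vs-Black contrast fields;
#'   0 switches spatial polarisation off.
#' @param polarCor correlation between the White and Black polarisation
#'   fields (1 = exact mirror images; lower values leave the two cluster
#'   patterns partially distinct, as in real cities where the two "high
#'   clustering" maps overlap imperfectly).
#' @param fieldScale sd multiplier of each group's own latent field;
#'   either a scalar or a named per-group vector.
#' @param smoothingSteps neighbour-averaging passes applied to every latent
#'   field; 0 switches spatial smoothing off entirely.
#' @param sesMeans,sesSds,sesRaceCor per-SES-covariate target mean, sd and
#'   correlation with the (standardised) Black share.
#' @param trueBeta0 true intercept (log scale).
#' @param trueBeta named true log-rate effects for the model-4 covariate
#'   set (cluster covariates act on the 0/1 high-vs-low coding).
#' @param trueTauU,trueTauV true structured / unstructured precisions.
#' @param truePi0 true structural-zero probability in \[0, 1).
#' @param popRange tract populations are drawn log-uniformly in this range.
#' @param offsetRule offset convention, see [modelSpec()].
#' @return a `SimulationConfig` list.
#' @export
simConfig <- function(nx = 12L, ny = 8L,
                      baseline = c(white = 1.3, black = 1.5,
                                   asian = -1.2, hispanic = 0),
                      polarization = 0.9,
                      polarCor = 0.3,
                      fieldScale = c(white = 1.0, black = 1.0,
                                     asian = 1.2, hispanic = 1.2),
                      smoothingSteps = 1L,
                      sesMeans = c(pctPoverty = 36.4, pctSnap = 36.8,
                                   pctNoVehicle = 25.5, pctVacant = 21.5,
                                   pctCollege = 9.5),
                      sesSds = c(pctPoverty = 15.0, pctSnap = 15.6,
                                 pctNoVehicle = 14.7, pctVacant = 10.4,
                                 pctCollege = 7.2),
                      sesRaceCor = c(pctPoverty = 0.55, pctSnap = 0.6,
                                     pctNoVehicle = 0.5, pctVacant = 0.45,
                                     pctCollege = -0.5),
                      trueBeta0 = 0.3,
                      trueBeta = c(entropyScore = -0.5,
                                   clusterBlack = -0.5,
                                   clusterWhite = 0.5,
                                   pctAsian = 0.02, pctHispanic = 0.02,
                                   pctPoverty = 0, pctSnap = 0,
                                   pctNoVehicle = 0, pctVacant = 0,
                                   pctCollege = 0),
                      trueTauU = 10, trueTauV = 25, truePi0 = 0.15,
                      popRange = c(1000, 8000),
                      offsetRule = "population") {
  stopifnot(nx >= 2L, ny >= 2L, trueTauU > 0, trueTauV > 0,
            truePi0 >= 0, truePi0 < 1, popRange[1L] > 0,
            popRange[2L] >= popRange[1L])
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 baseline = baseline, polarization = polarization,
                 polarCor = polarCor, fieldScale = fieldScale,
                 smoothingSteps = as.integer(smoothingSteps),
                 sesMeans = sesMeans, sesSds = sesSds,
                 sesRaceCor = sesRaceCor,
                 trueBeta0 = trueBeta0, trueBeta = trueBeta,
                 trueTauU = trueTauU, trueTauV = trueTauV,
                 truePi0 = truePi0, popRange = popRange,
                 offsetRule = offsetRule),
            class = "SimulationConfig")
}

#' Rectangular lattice of unit-square tracts
#'
#' Deterministic: `nx * ny` unit squares in row-major order with ids
#' `T001, T002, ...`, plus their queen-contiguity [AreaGraph-class]
#' (diagonal touch counts).
#'
#' @param config a [simConfig()] (only `nx`, `ny` are used).
#' @return list with `graph` (an [AreaGraph-class]) and `polygons` (named
#'   list of 4 x 2 vertex matrices usable by [areaGraphFromPolygons()]).
#' @export
simulateLattice <- function(config = simConfig()) {
  nx <- config$nx; ny <- config$ny
  n <- nx * ny
  ids <- sprintf("T%03d", seq_len(n))
  polys <- vector("list", n)
  nb <- vector("list", n)
  cellId <- function(r, c) (r - 1L) * nx + c
  for (r in seq_len(ny)) {
    for (c in seq_len(nx)) {
      i <- cellId(r, c)
      polys[[i]] <- cbind(x = c(c - 1, c, c, c - 1), y = c(r - 1, r - 1, r, r))
      rr <- rep(r + (-1):1, each = 3L); cc <- rep(c + (-1):1, times = 3L)
      keep <- rr >= 1L & rr <= ny & cc >= 1L & cc <= nx & !(rr == r & cc == c)
      nb[[i]] <- ids[cellId(rr[keep], cc[keep])]
    }
  }
  names(polys) <- ids
  list(graph = areaGraph(ids, nb), polygons = polys)
}

## smoothed standardised Gaussian field on the graph
.smoothField <- function(graph, steps) {
  n <- nAreas(graph)
  z <- rnorm(n)
  if (steps > 0L) {
    for (s in seq_len(steps)) {
      z <- vapply(seq_len(n), function(i) {
        js <- graph@adj[[i]]
        (z[i] + sum(z[js])) / (1 + length(js))
      }, numeric(1L))
    }
  }
  if (sd(z) > 0) (z - mean(z)) / sd(z) else z
}

#' Simulate spatially autocorrelated racial composition
#'
#' Each of the four groups gets a latent score
#' `baseline_r + fieldScale * field_r`, where `field_r` is a smoothed
#' standardised Gaussian field on the graph; a shared polarisation field is
#' added to the White score and subtracted from the Black score, creating
#' contiguous White-majority and Black-majority regions. A softmax turns
#' the scores into per-tract proportions (summing to 1 exactly).
#'
#' @param graph an [AreaGraph-class].
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return data.frame keyed by `areaId` with proportion columns `white`,
#'   `black`, `asian`, `hispanic` and a `population` column.
#' @export
simulateComposition <- function(graph, config = simConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  n <- nAreas(graph)
  groups <- names(config$baseline)
  # two partially correlated polarisation fields: White-majority and
  # Black-majority regions are contiguous but not exact mirror images
  f1 <- .smoothField(graph, config$smoothingSteps)
  f2 <- .smoothField(graph, config$smoothingSteps)
  rho <- config$polarCor
  fW <- f1
  fB <- rho * f1 + sqrt(1 - rho^2) * f2
  fs <- rep_len(config$fieldScale, length(groups))
  names(fs) <- groups
  if (!is.null(names(config$fieldScale)) && all(groups %in% names(config$fieldScale))) {
    fs <- config$fieldScale[groups]
  }
  latent <- sapply(groups, function(g) {
    config$baseline[[g]] + fs[[g]] * .smoothField(graph, config$smoothingSteps)
  })
  latent[, "white"] <- latent[, "white"] + config$polarization * fW
  latent[, "black"] <- latent[, "black"] - config$polarization * fB
  ex <- exp(latent - apply(latent, 1L, max))
  props <- ex / rowSums(ex)
  pop <- round(exp(runif(n, log(config$popRange[1L]), log(config$popRange[2L]))))
  out <- data.frame(areaId = areaIds(graph), props, population = pop,
                    row.names = NULL)
  out
}

#' Simulate SES covariates correlated with the Black share
#'
#' Five percentage-scale covariates (poverty, SNAP recipiency, no-vehicle
#' households, vacant housing, college-educated), each a linear function of
#' the standardised Black share plus independent noise with the configured
#' correlation, shifted/scaled to its target mean and sd and clipped to
#' \[0, 100\]. At the default settings the generated design passes the
#' VIF < 6 screen.
#'
#' @param composition output of [simulateComposition()].
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return data.frame keyed by `areaId` with the five `pct*` columns.
#' @export
simulateCovariates <- function(composition, config = simConfig(), seed = 2L) {
  set.seed(as.integer(seed))
  zb <- composition$black
  zb <- if (sd(zb) > 0) (zb - mean(zb)) / sd(zb) else zb * 0
  n <- length(zb)
  out <- data.frame(areaId = composition$areaId)
  for (nm in names(config$sesMeans)) {
    rho <- config$sesRaceCor[[nm]]
    x <- config$sesMeans[[nm]] + config$sesSds[[nm]] *
      (rho * zb + sqrt(1 - rho^2) * rnorm(n))
    out[[nm]] <- pmin(100, pmax(0, x))
  }
  out
}

#' Simulate store counts from the ZIP-BYM generative law
#'
#' Draws the structured effect `u` exactly from the intrinsic CAR law
#' (eigen-decomposition of the graph Laplacian, sum-to-zero per component),
#' `v` iid Normal(0, 1/tauV), forms
#' `lambda = exp(beta0 + X beta + u + v + offset)`, then zeroes each count
#' with probability `pi0` and otherwise draws Poisson(lambda).
#'
#' @param graph an [AreaGraph-class].
#' @param design data.frame with the covariate columns named in
#'   `config$trueBeta` (cluster columns may be factors) and a `population`
#'   column for the offset.
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return list with `areaTable` (the design plus `storeCount`) and `truth`
#'   (list of all latent values used: `beta0`, `beta`, `u`, `v`, `tauU`,
#'   `tauV`, `pi0`, `offset`, `structuralZero`).
#' @export
simulateCounts <- function(graph, design, config = simConfig(), seed = 3L) {
  set.seed(as.integer(seed))
  n <- nAreas(graph)
  beta <- config$trueBeta
  missing <- setdiff(names(beta), names(design))
  if (length(missing)) stop("design lacks column(s): ", paste(missing, collapse = ", "))
  spec4 <- modelSpec(4L, offsetRule = config$offsetRule)
  spec4$covariates <- names(beta)
  X <- designMatrix(design, spec4)
  u <- icarSample(graph, config$trueTauU)
  v <- rnorm(n, 0, 1 / sqrt(config$trueTauV))
  offset <- offsetVector(design$population, config$offsetRule)
  eta <- linearPredictor(c(config$trueBeta0, beta[colnames(X)]), X, u, v, offset)
  sz <- rbinom(n, 1L, config$truePi0) == 1L
  y <- ifelse(sz, 0L, rpois(n, exp(eta)))
  areaTable <- cbind(design, storeCount = as.integer(y))
  list(areaTable = areaTable,
       truth = list(beta0 = config$trueBeta0, beta = beta,
                    u = unname(u), v = v,
                    tauU = config$trueTauU, tauV = config$trueTauV,
                    pi0 = config$truePi0, offset = offset,
                    structuralZero = sz))
}

#' Generate a complete synthetic study
#'
#' Runs the full generative chain: lattice, composition, segregation
#' features (computed with the package's own metrics, so the regression
#' covariates are exactly what the analysis pipeline would compute),
#' SES covariates, and ZIP-BYM counts. The one `seed` drives every stage.
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return list with `graph`, `polygons`, `composition`, `areaTable` (one
#'   row per area: id, population, all covariates, `storeCount`) and
#'   `truth`.
#' @export
simulateStudy <- function(config = simConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  stageSeeds <- sample.int(.Machine$integer.max - 1L, 3L)
  lattice <- simulateLattice(config)
  composition <- simulateComposition(lattice$graph, config, seed = stageSeeds[1L])
  feats <- segregationFeatures(
    composition[, c("white", "black", "asian", "hispanic")],
    lattice$graph, population = composition$population)
  ses <- simulateCovariates(composition, config, seed = stageSeeds[2L])
  design <- cbind(feats[, c("areaId", "entropyScore", "clusterBlack",
                            "clusterWhite", "pctAsian", "pctHispanic")],
                  ses[, names(config$sesMeans), drop = FALSE],
                  population = composition$population)
  counts <- simulateCounts(lattice$graph, design, config, seed = stageSeeds[3L])
  list(graph = lattice$graph, polygons = lattice$polygons,
       composition = composition, areaTable = counts$areaTable,
       truth = counts$truth, seed = as.integer(seed), config = config)
}

#' Write a synthetic study bundle to disk
#'
#' Emits plain-text artefacts: `area_table.csv`, `composition.csv`,
#' `edges.csv`, `geometry.geojson` and `truth.json` (the contract for
#' parameter-recovery tests).
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticBundle <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$areaTable, file.path(dir, "area_table.csv"), row.names = FALSE)
  write.csv(study$composition, file.path(dir, "composition.csv"), row.names = FALSE)
  writeEdgeList(study$graph, file.path(dir, "edges.csv"))
  writeGeoJSON(study$polygons, file.path(dir, "geometry.geojson"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' @param polygons named list of vertex matrices (as produced by
#'   [simulateLattice()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeoJSON <- function(polygons, path) {
  features <- lapply(names(polygons), function(id) {
    ring <- polygons[[id]]
    ring <- rbind(ring, ring[1L, ])   # close the ring
    list(type = "Feature",
         properties = list(id = id),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) as.numeric(ring[i, 1:2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
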