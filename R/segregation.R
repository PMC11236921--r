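## Multigroup entropy segregation, local G* clustering, VIF screening.

#' Entropy (diversity) of a racial composition vector
#'
#' Shannon entropy `E = -sum(p * log(p))` over groups with positive share,
#' natural log. For R groups the maximum is `log(R)`, attained at the
#' uniform composition; a single-group area scores 0.
#'
#' @param proportions numeric vector of group shares, nonnegative, summing
#'   to 1 (tolerance 1e-9).
#' @return nonnegative scalar entropy (nats).
#' @export
tractEntropy <- function(proportions) {
  p <- as.numeric(proportions)
  if (any(!is.finite(p)) || any(p < 0)) stop("proportions must be finite and nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1 (got ", sum(p), ")")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Tract-level entropy deviation score
#'
#' How far an area's diversity falls below the city's:
#' `h = max(0, (E - E_i) / E)` where `E` is the citywide entropy and `E_i`
#' the area's. 0 when the area is at least as diverse as the city, 1 when
#' the area holds a single group. This is the per-tract covariate entering
#' the regression ("entropy index" in reporting, range 0-1).
#'
#' @param tractProportions group shares for the area.
#' @param cityProportions group shares for the whole city; its entropy must
#'   be positive (a single-group city has no diversity to deviate from).
#' @return scalar in \[0, 1\].
#' @export
entropyDeviationScore <- function(tractProportions, cityProportions) {
  E <- tractEntropy(cityProportions)
  if (E <= 0) stop("citywide entropy is zero (single-group city): score undefined")
  Ei <- tractEntropy(tractProportions)
  max(0, (E - Ei) / E)
}

#' Citywide multigroup entropy index (Theil's H)
#'
#' Population-weighted average deviation of tract diversity from citywide
#' diversity: `H = sum_i t_i * (E - E_i) / (E * T)` with `t_i` the tract
#' population, `T` the total, `E` the entropy of the pooled composition and
#' `E_i` each tract's entropy. 0 when every tract mirrors the city
#' (integration), 1 when every tract holds a single group (segregation).
#'
#' Zero-population tracts carry no weight and are dropped with a warning.
#'
#' @param counts numeric matrix of group counts, one row per area, one
#'   column per group (or a matrix of proportions if `population` is given).
#' @param population optional vector of tract populations; defaults to
#'   `rowSums(counts)` (i.e. `counts` are person counts).
#' @return scalar H in \[0, 1\].
#' @export
citywideEntropyIndex <- function(counts, population = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) stop("counts must be finite and nonnegative")
  if (is.null(population)) population <- rowSums(counts)
  if (length(population) != nrow(counts)) stop("population length must match rows of counts")
  if (sum(population) <= 0) stop("total population is zero")
  if (any(population == 0)) {
    warning(sum(population == 0), " zero-population tract(s) dropped from the entropy index")
    counts <- counts[population > 0, , drop = FALSE]
    population <- population[population > 0]
  }
  groupTotals <- colSums(counts / rowSums(counts) * population)
  E <- tractEntropy(groupTotals / sum(groupTotals))
  if (E <= 0) stop("citywide entropy is zero (single-group city)")
  Ei <- apply(counts, 1L, function(r) tractEntropy(r / sum(r)))
  sum(population * (E - Ei)) / (E * sum(population))
}

#' Getis-Ord local G* z-scores
#'
#' Local concentration statistic for a surface over the areal graph, with
#' binary contiguity weights including self (`w_ii = 1`, the starred
#' variant):
#' `z_i = (sum_j w_ij x_j - xbar W_i) / (S * sqrt((n W_i - W_i^2)/(n - 1)))`
#' with `W_i = sum_j w_ij`, `xbar` the global mean and
#' `S = sqrt(mean(x^2) - xbar^2)` the global (population) standard
#' deviation. Positive z marks a local cluster of high values, negative z a
#' cluster of low values.
#'
#' A constant surface has no variance: all z are defined as 0, with a
#' warning. An area whose weight set spans the whole map (`W_i = n`) also
#' has a degenerate denominator and gets z = 0.
#'
#' @param values numeric vector per area, in graph order.
#' @param graph an [AreaGraph-class] (>= 3 areas).
#' @return numeric vector of z-scores, named by area id.
#' @export
localGstar <- function(values, graph) {
  n <- nAreas(graph)
  if (n < 3L) stop("local G* needs at least 3 areas")
  x <- as.numeric(values)
  if (length(x) != n) stop("length(values) must equal the number of areas")
  if (any(!is.finite(x))) stop("values must be finite")
  xbar <- mean(x)
  S <- sqrt(mean(x^2) - xbar^2)
  if (S == 0) {
    warning("constant surface: all local G* z-scores set to 0")
    return(setNames(rep(0, n), graph@areaIds))
  }
  z <- numeric(n)
  for (i in seq_len(n)) {
    js <- c(i, graph@adj[[i]])
    Wi <- length(js)
    den <- S * sqrt((n * Wi - Wi^2) / (n - 1))
    z[i] <- if (den == 0) 0 else (sum(x[js]) - xbar * Wi) / den
  }
  setNames(z, graph@areaIds)
}

#' Classify cluster membership from local G* z-scores
#'
#' An area is a "high" cluster when its z-score is strictly positive and a
#' "low" cluster otherwise (z = 0 ties break to "low").
#'
#' @param z numeric vector of finite z-scores.
#' @return factor with levels `low`, `high`, names preserved.
#' @export
classifyClusters <- function(z) {
  if (any(!is.finite(z))) stop("z-scores must be finite")
  factor(ifelse(z > 0, "high", "low"), levels = c("low", "high"))
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from the least-squares
#' regression (with intercept) of covariate k on all the others. Values at
#' or above `threshold` are flagged as collinear; an exactly collinear
#' column is reported as `Inf`.
#'
#' @param design numeric matrix or data.frame of covariates (>= 2 columns,
#'   more rows than columns, no zero-variance column).
#' @param threshold flag level; the screening convention used here is 6.
#' @return data.frame with columns `covariate`, `vif`, `flagged`.
#' @export
computeVif <- function(design, threshold = 6) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (ncol(X) < 2L) stop("need at least 2 covariates")
  if (nrow(X) <= ncol(X)) stop("need more rows than covariates")
  if (any(!is.finite(X))) stop("design must be finite")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vif <- vapply(seq_len(ncol(X)), function(k) {
    fit <- lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  data.frame(covariate = colnames(X), vif = vif,
             flagged = vif >= threshold, row.names = NULL)
}

#' Segregation feature table for the regression models
#'
#' Computes, per area: the entropy deviation score, local G* z-scores and
#' high/low cluster classes for the Black and White shares, and the Asian
#' and Hispanic percentages — the covariate block of the
#' segregation-only model.
#'
#' @param composition data.frame or matrix of group counts with columns
#'   `white`, `black`, `asian`, `hispanic` (case-insensitive), rows in graph
#'   order.
#' @param graph an [AreaGraph-class].
#' @param population optional population per area; defaults to row sums.
#' @return data.frame keyed by `areaId` with columns `entropyScore`,
#'   `gstarZBlack`, `gstarZWhite`, `clusterBlack`, `clusterWhite`,
#'   `pctAsian`, `pctHispanic`.
#' @export
segregationFeatures <- function(composition, graph, population = NULL) {
  comp <- as.matrix(as.data.frame(composition)[,
    vapply(as.data.frame(composition), is.numeric, logical(1L)), drop = FALSE])
  colnames(comp) <- tolower(colnames(comp))
  need <- c("white", "black", "asian", "hispanic")
  missing <- setdiff(need, colnames(comp))
  if (length(missing)) stop("composition lacks column(s): ", paste(missing, collapse = ", "))
  comp <- comp[, need, drop = FALSE]
  if (nrow(comp) != nAreas(graph)) stop("composition rows must match graph areas")
  if (is.null(population)) population <- rowSums(comp)
  shares <- comp / rowSums(comp)
  cityTotals <- colSums(shares * population)
  cityShare <- cityTotals / sum(cityTotals)
  h <- apply(shares, 1L, entropyDeviationScore, cityProportions = cityShare)
  zB <- localGstar(shares[, "black"], graph)
  zW <- localGstar(shares[, "white"], graph)
  data.frame(
    areaId       = areaIds(graph),
    entropyScore = h,
    gstarZBlack  = unname(zB),
    gstarZWhite  = unname(zW),
    clusterBlack = classifyClusters(unname(zB)),
    clusterWhite = classifyClusters(unname(zW)),
    pctAsian     = 100 * shares[, "asian"],
    pctHispanic  = 100 * shares[, "hispanic"],
    row.names    = NULL
  )
}
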