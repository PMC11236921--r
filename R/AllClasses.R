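#' Areal contiguity graph
#'
#' An `AreaGraph` stores the neighbourhood structure of a set of areal units
#' (census tracts): which areas touch which. It is the object on which the
#' intrinsic CAR (ICAR) smoothing prior and the local G* statistic are
#' defined. Areas are kept in sorted order of their identifiers, and every
#' vector aligned to a graph uses that order.
#'
#' @slot areaIds character vector of unique area identifiers, sorted.
#' @slot adj list of integer vectors; `adj[[i]]` holds the (1-based) indices
#'   of the neighbours of area `i`. Symmetric, no self-loops.
#' @slot componentId integer vector giving the connected component each area
#'   belongs to (1-based, components numbered by smallest member).
#'
#' @details Degree-0 areas ("islands") are permitted but flagged at
#' construction time with a warning: the ICAR prior is undefined for them,
#' so their structured effect is fixed at zero throughout the package.
#'
#' @seealso [areaGraph()], [areaGraphFromEdges()], [areaGraphFromPolygons()],
#'   [icarEnergy()]
#' @export
setClass("AreaGraph",
  representation(
    areaIds     = "character",
    adj         = "list",
    componentId = "integer"
  )
)

setValidity("AreaGraph", function(object) {
  n <- length(object@areaIds)
  if (anyDuplicated(object@areaIds)) {
    return("area ids must be unique")
  }
  if (length(object@adj) != n || length(object@componentId) != n) {
    return("adjacency list and component vector must match the number of areas")
  }
  for (i in seq_len(n)) {
    nb <- object@adj[[i]]
    if (any(nb < 1L | nb > n)) return("neighbour index out of range")
    if (any(nb == i)) return(sprintf("self-loop at area '%s'", object@areaIds[i]))
    if (anyDuplicated(nb)) return(sprintf("duplicated neighbour at area '%s'", object@areaIds[i]))
    for (j in nb) {
      if (!(i %in% object@adj[[j]])) {
        return(sprintf("adjacency is not symmetric between '%s' and '%s'",
                       object@areaIds[i], object@areaIds[j]))
      }
    }
  }
  TRUE
})

#' Posterior samples from a ZIP-BYM fit
#'
#' Container for retained MCMC draws of the zero-inflated Poisson BYM
#' regression: regression coefficients `beta` (including the intercept),
#' structured spatial effects `u`, unstructured effects `v`, the precisions
#' `tauU` and `tauV`, and the zero-inflation probability `pi0`. Draws from
#' all chains are stacked row-wise; the `chain` vector says which chain each
#' retained draw came from.
#'
#' @slot beta numeric matrix, draws x coefficients, with column names.
#' @slot u numeric matrix, draws x areas (structured effect, sum-to-zero per
#'   connected component).
#' @slot v numeric matrix, draws x areas (unstructured effect).
#' @slot tauU,tauV numeric vectors of precision draws (positive).
#' @slot pi0 numeric vector of zero-inflation probability draws, in (0, 1).
#' @slot chain integer vector, chain index per retained draw.
#' @slot areaIds character vector of area identifiers (column order of `u`,`v`).
#' @slot settings list recording seed, iteration counts, acceptance rates
#'   and the model specification used.
#'
#' @seealso [fitMcmc()], [summarizePosterior()], [dic()],
#'   [exceedanceProbability()]
#' @export
setClass("ZipBymFit",
  representation(
    beta     = "matrix",
    u        = "matrix",
    v        = "matrix",
    tauU     = "numeric",
    tauV     = "numeric",
    pi0      = "numeric",
    chain    = "integer",
    areaIds  = "character",
    settings = "list"
  )
)

setValidity("ZipBymFit", function(object) {
  m <- nrow(object@beta)
  if (nrow(object@u) != m || nrow(object@v) != m ||
      length(object@tauU) != m || length(object@tauV) != m ||
      length(object@pi0) != m || length(object@chain) != m) {
    return("all draw containers must have the same number of retained draws")
  }
  if (ncol(object@u) != length(object@areaIds)) {
    return("u must have one column per area")
  }
  if (any(object@tauU <= 0) || any(object@tauV <= 0)) {
    return("precision draws must be positive")
  }
  if (any(object@pi0 <= 0 | object@pi0 >= 1)) {
    return("pi0 draws must lie strictly in (0, 1)")
  }
  # sum-to-zero per component, islands excluded
  comp <- object@settings$componentId
  isl  <- object@settings$island
  if (!is.null(comp) && m > 0) {
    keep <- if (is.null(isl)) rep(TRUE, ncol(object@u)) else !isl
    for (k in unique(comp[keep])) {
      idx <- which(comp == k & keep)
      s <- rowSums(object@u[, idx, drop = FALSE])
      if (any(abs(s) > 1e-8)) {
        return("structured effect u must sum to zero within each connected component")
      }
    }
  }
  TRUE
})
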