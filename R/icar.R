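## Intrinsic CAR (Besag) mathematics on an AreaGraph.

#' ICAR pairwise-difference energy
#'
#' The quadratic form `sum over neighbour pairs i~j of (u_i - u_j)^2`, taken
#' over unordered pairs. This is the exponent kernel of the intrinsic
#' conditional autoregressive (ICAR) prior used for the structured spatial
#' effect: the log-density is `-(tau_u / 2) * energy` up to a constant.
#' Equal to `t(u) %*% (D - A) %*% u` where `D` is the degree matrix and `A`
#' the adjacency matrix.
#'
#' Islands (degree-0 areas) contribute nothing: they appear in no pair.
#'
#' @param u numeric vector, one value per area, in the graph's id order.
#' @param graph an [AreaGraph-class].
#' @return nonnegative scalar; zero iff `u` is constant on every connected
#'   component.
#' @export
icarEnergy <- function(u, graph) {
  n <- nAreas(graph)
  if (length(u) != n) {
    stop("length(u) = ", length(u), " but the graph has ", n, " areas")
  }
  if (any(!is.finite(u))) stop("u must be finite")
  e <- 0
  for (i in seq_len(n)) {
    js <- graph@adj[[i]]
    js <- js[js > i]
    if (length(js)) e <- e + sum((u[i] - u[js])^2)
  }
  e
}

#' Unnormalised ICAR log-density
#'
#' `-(tauU / 2) * icarEnergy(u, graph)`. The prior is improper: it is
#' invariant under adding a constant to `u` within a connected component, so
#' samplers impose a sum-to-zero constraint per component. The
#' `tauU`-dependent normalising factor `(rank(L)/2) * log(tauU)` is *not*
#' included here; [logPosterior()] adds it where `tauU` itself is a
#' parameter.
#'
#' @inheritParams icarEnergy
#' @param tauU positive precision of the structured effect.
#' @return scalar log-density up to an additive constant.
#' @export
icarLogpdfUnnorm <- function(u, graph, tauU) {
  if (!is.numeric(tauU) || length(tauU) != 1L || !is.finite(tauU) || tauU <= 0) {
    stop("tauU must be a positive scalar")
  }
  -(tauU / 2) * icarEnergy(u, graph)
}

#' Rank of the ICAR precision structure
#'
#' Number of non-island areas minus the number of connected components they
#' form: the rank of the graph Laplacian restricted to non-islands. This is
#' the exponent that multiplies `log(tau_u) / 2` in the proper part of the
#' ICAR density, and the degrees of freedom entering the Gibbs update of
#' `tau_u`.
#'
#' @param graph an [AreaGraph-class].
#' @return integer rank.
#' @export
icarRank <- function(graph) {
  deg <- vapply(graph@adj, length, integer(1L))
  keep <- deg > 0L
  sum(keep) - length(unique(graph@componentId[keep]))
}

#' Exact draw from the intrinsic CAR law
#'
#' Samples `u ~ ICAR(graph, tauU)` under the sum-to-zero constraint per
#' connected component, by eigen-decomposing the graph Laplacian `L = D - A`
#' and drawing independent normals on its non-null eigenspace with variances
#' `1 / (tauU * lambda_k)`. Islands get `u = 0`.
#'
#' @param graph an [AreaGraph-class].
#' @param tauU positive precision.
#' @param nDraws number of independent fields to draw.
#' @return numeric matrix `nDraws x nAreas(graph)` (a vector when
#'   `nDraws = 1`), columns named by area id. Uses the current RNG state.
#' @export
icarSample <- function(graph, tauU, nDraws = 1L) {
  if (tauU <= 0) stop("tauU must be positive")
  n <- nAreas(graph)
  L <- graphLaplacian(graph)
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  lam <- eg$values[pos]
  z <- matrix(rnorm(nDraws * length(lam)), nDraws, length(lam))
  u <- z %*% (t(V) * (1 / sqrt(tauU * lam)))
  # islands: no structured effect
  deg <- vapply(graph@adj, length, integer(1L))
  u[, deg == 0L] <- 0
  # exact sum-to-zero per component (numerical cleanup)
  for (k in unique(graph@componentId[deg > 0L])) {
    idx <- which(graph@componentId == k & deg > 0L)
    u[, idx] <- u[, idx, drop = FALSE] -
      rowMeans(u[, idx, drop = FALSE])
  }
  colnames(u) <- graph@areaIds
  if (nDraws == 1L) u[1L, ] else u
}
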