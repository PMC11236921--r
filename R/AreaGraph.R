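## Construction and interrogation of the areal contiguity graph.

#' Build an AreaGraph from an adjacency specification
#'
#' Low-level constructor: takes area ids and a neighbour list keyed the same
#' way, symmetrises nothing — the input must already be symmetric. Most users
#' want [areaGraphFromEdges()] or [areaGraphFromPolygons()].
#'
#' @param areaIds character (or coercible) vector of unique identifiers.
#' @param neighbors list, parallel to `areaIds`, of character vectors naming
#'   each area's neighbours.
#' @return An [AreaGraph-class] object, areas sorted by id.
#' @export
areaGraph <- function(areaIds, neighbors) {
  areaIds <- as.character(areaIds)
  if (anyDuplicated(areaIds)) {
    stop("duplicate area ids: ",
         paste(unique(areaIds[duplicated(areaIds)]), collapse = ", "))
  }
  ord <- order(areaIds)
  ids <- areaIds[ord]
  neighbors <- neighbors[ord]
  idx <- setNames(seq_along(ids), ids)
  adj <- lapply(neighbors, function(nb) {
    nb <- as.character(nb)
    unknown <- setdiff(nb, ids)
    if (length(unknown)) stop("unknown neighbour id(s): ", paste(unknown, collapse = ", "))
    sort(unname(idx[nb]))
  })
  g <- new("AreaGraph", areaIds = ids, adj = adj,
           componentId = .components(adj, length(ids)))
  validObject(g)
  deg <- nNeighbors(g)
  if (any(deg == 0L)) {
    warning("island area(s) with no neighbours: ",
            paste(ids[deg == 0L], collapse = ", "))
  }
  g
}

## connected components by breadth-first search, numbered by smallest member
.components <- function(adj, n) {
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      for (j in adj[[i]]) {
        if (comp[j] == 0L) { comp[j] <- k; queue <- c(queue, j) }
      }
    }
  }
  comp
}

#' Build an AreaGraph from an edge list
#'
#' @param edges two-column data.frame (or matrix) of area-id pairs, one row
#'   per contiguity link. Order and duplication are ignored; the graph is
#'   symmetrised.
#' @param areaIds optional full set of area ids, so that areas with no edges
#'   (islands) are retained; defaults to the ids appearing in `edges`.
#' @return An [AreaGraph-class].
#' @export
areaGraphFromEdges <- function(edges, areaIds = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("edge list needs two columns (id_a, id_b)")
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  if (any(a == b)) stop("self-loop edges are not allowed")
  if (is.null(areaIds)) areaIds <- unique(c(a, b))
  areaIds <- sort(as.character(areaIds))
  nb <- lapply(setNames(areaIds, areaIds), function(id) {
    unique(c(b[a == id], a[b == id]))
  })
  areaGraph(areaIds, nb)
}

#' Read an adjacency edge list from a delimited text file
#'
#' Expects two columns `id_a`, `id_b` (header optional when `header = FALSE`).
#'
#' @param path file path.
#' @param header logical, whether the file has a header row.
#' @inheritParams areaGraphFromEdges
#' @return An [AreaGraph-class].
#' @export
readEdgeList <- function(path, areaIds = NULL, header = TRUE) {
  areaGraphFromEdges(read.csv(path, header = header,
                              colClasses = "character"), areaIds = areaIds)
}

#' Write a graph's edges as a delimited text file
#'
#' One row per unordered neighbour pair, columns `id_a`, `id_b`.
#'
#' @param graph an [AreaGraph-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  e <- edgeList(graph)
  write.csv(e, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Queen-contiguity graph from polygon geometries
#'
#' Two areas are neighbours when their boundaries share at least one point
#' (queen contiguity). Shared points are detected as shared polygon vertices
#' after rounding coordinates to `digits` decimal places, which is exact for
#' lattices and for polygon layers whose boundaries use conforming vertices
#' (as census-tract layers do).
#'
#' @param polygons named list, one element per area: a two-column numeric
#'   matrix of (x, y) vertex coordinates (rings may be closed or open;
#'   multipolygons may be given as a list of such matrices).
#' @param digits coordinate rounding used for vertex matching.
#' @return An [AreaGraph-class]; a disconnected result carries a warning via
#'   its island/connectivity reporting.
#' @export
areaGraphFromPolygons <- function(polygons, digits = 9L) {
  if (length(polygons) == 0L) stop("empty polygon set")
  ids <- names(polygons)
  if (is.null(ids) || any(!nzchar(ids))) stop("polygons must be named by area id")
  if (anyDuplicated(ids)) {
    stop("duplicate area ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vertexKeys <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    if (is.matrix(p)) p <- list(p)
    keys <- unlist(lapply(p, function(ring) {
      ring <- as.matrix(ring)
      if (!is.numeric(ring) || ncol(ring) < 2L || nrow(ring) < 3L ||
          any(!is.finite(ring[, 1:2]))) {
        stop("invalid geometry for area '", ids[i], "'")
      }
      paste(round(ring[, 1L], digits), round(ring[, 2L], digits), sep = "|")
    }))
    unique(keys)
  })
  names(vertexKeys) <- ids
  # invert: vertex -> areas touching it
  vert <- data.frame(
    key  = unlist(vertexKeys, use.names = FALSE),
    area = rep(ids, lengths(vertexKeys)),
    stringsAsFactors = FALSE
  )
  byKey <- split(vert$area, vert$key)
  pairs <- do.call(rbind, lapply(byKey[lengths(byKey) > 1L], function(as) {
    t(utils::combn(sort(as), 2L))
  }))
  if (is.null(pairs)) {
    pairs <- matrix(character(0), ncol = 2L)
  }
  pairs <- unique(as.data.frame(pairs, stringsAsFactors = FALSE))
  if (nrow(pairs) == 0L) {
    # no contact anywhere: all-island graph (warns about the islands)
    return(areaGraph(ids, rep(list(character(0)), length(ids))))
  }
  areaGraphFromEdges(pairs, areaIds = ids)
}

#' Queen-contiguity graph from a GeoJSON polygon layer
#'
#' Reads a GeoJSON `FeatureCollection` of `Polygon`/`MultiPolygon` features
#' and builds the queen-contiguity [AreaGraph-class] via
#' [areaGraphFromPolygons()].
#'
#' @param path path to a GeoJSON file.
#' @param idProperty name of the feature property holding the area id.
#' @inheritParams areaGraphFromPolygons
#' @return An [AreaGraph-class].
#' @export
areaGraphFromGeoJSON <- function(path, idProperty = "id", digits = 9L) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list()
  for (f in gj$features) {
    id <- f$properties[[idProperty]]
    if (is.null(id)) stop("feature without property '", idProperty, "'")
    geom <- f$geometry
    ringsToMat <- function(rings) lapply(rings, function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    })
    mats <- switch(geom$type,
      Polygon      = ringsToMat(geom$coordinates),
      MultiPolygon = unlist(lapply(geom$coordinates, ringsToMat), recursive = FALSE),
      stop("unsupported geometry type '", geom$type, "' for area '", id, "'")
    )
    polys[[as.character(id)]] <- mats
  }
  areaGraphFromPolygons(polys, digits = digits)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn areaGraph Area identifiers, in the graph's canonical order.
#' @param graph an [AreaGraph-class].
#' @export
areaIds <- function(graph) graph@areaIds

#' @describeIn areaGraph Number of areas.
#' @export
nAreas <- function(graph) length(graph@areaIds)

#' @describeIn areaGraph Integer degree (neighbour count) per area, named.
#' @export
nNeighbors <- function(graph) {
  setNames(vapply(graph@adj, length, integer(1L)), graph@areaIds)
}

#' @describeIn areaGraph Neighbour id list, named by area id.
#' @export
neighborList <- function(graph) {
  setNames(lapply(graph@adj, function(nb) graph@areaIds[nb]), graph@areaIds)
}

#' @describeIn areaGraph TRUE when the graph has a single connected component.
#' @export
isConnected <- function(graph) length(unique(graph@componentId)) == 1L

#' @describeIn areaGraph Connected-component index per area, named.
#' @export
componentIds <- function(graph) setNames(graph@componentId, graph@areaIds)

#' @describeIn areaGraph Unordered neighbour pairs as a two-column data.frame.
#' @export
edgeList <- function(graph) {
  n <- nAreas(graph)
  rows <- list()
  for (i in seq_len(n)) {
    js <- graph@adj[[i]]
    js <- js[js > i]
    if (length(js)) rows[[length(rows) + 1L]] <-
      data.frame(id_a = graph@areaIds[i], id_b = graph@areaIds[js],
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(id_a = character(0), id_b = character(0)))
  }
  do.call(rbind, rows)
}

#' Graph Laplacian D - A of an AreaGraph
#'
#' Dense matrix with degrees on the diagonal and -1 for each neighbour pair;
#' the ICAR energy is the quadratic form `0.5 * t(u) %*% L %*% u ... ` times
#' two conventions, see [icarEnergy()].
#'
#' @param graph an [AreaGraph-class].
#' @return numeric matrix, dimnames = area ids.
#' @export
graphLaplacian <- function(graph) {
  n <- nAreas(graph)
  L <- matrix(0, n, n, dimnames = list(graph@areaIds, graph@areaIds))
  for (i in seq_len(n)) {
    L[i, i] <- length(graph@adj[[i]])
    L[i, graph@adj[[i]]] <- -1
  }
  L
}

setMethod("show", "AreaGraph", function(object) {
  deg <- nNeighbors(object)
  cat("AreaGraph with", nAreas(object), "areas,",
      sum(deg) / 2L, "edges,",
      length(unique(object@componentId)), "component(s)\n")
  cat("  degree: min", min(deg), "/ mean", round(mean(deg), 2),
      "/ max", max(deg), "\n")
  if (any(deg == 0L)) {
    cat("  islands:", paste(object@areaIds[deg == 0L], collapse = ", "), "\n")
  }
  invisible(NULL)
})
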