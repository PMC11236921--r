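# Shared fixtures: small graphs and fast sampler settings.

# path graph a - b - c
pathGraph3 <- function() {
  areaGraph(c("a", "b", "c"), list("b", c("a", "c"), "b"))
}

# queen-contiguity grid via the lattice generator
gridGraph <- function(nx, ny) {
  simulateLattice(simConfig(nx = nx, ny = ny))$graph
}

# random connected-ish graph on n nodes: a spanning path plus random edges
randomGraph <- function(n, pExtra = 0.2) {
  ids <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(id_a = ids[-n], id_b = ids[-1])
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (runif(1) < pExtra) edges <- rbind(edges, data.frame(id_a = ids[i], id_b = ids[j]))
    }
  }
  areaGraphFromEdges(edges, areaIds = ids)
}

# fast sampler settings for tests
testSettings <- function(nIter = 2000L, nBurn = 1000L, nChains = 2L) {
  samplerSettings(nIter = nIter, nBurn = nBurn, nChains = nChains)
}

# a small fitted model on a default synthetic study
fitSmallStudy <- function(model = 2L, seed = 7L, ...) {
  study <- simulateStudy(seed = seed)
  fit <- fitMcmc(study$areaTable, study$graph, modelSpec(model),
                 settings = testSettings(...), seed = seed)
  list(study = study, fit = fit)
}

# dense independent G* oracle: straight transcription of the formula
gstarDense <- function(x, graph) {
  n <- nAreas(graph)
  A <- -graphLaplacian(graph); diag(A) <- 0
  W <- A + diag(n)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  Wi <- rowSums(W)
  num <- as.numeric(W %*% x) - xbar * Wi
  den <- S * sqrt((n * Wi - Wi^2) / (n - 1))
  unname(ifelse(den == 0, 0, num / den))
}
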