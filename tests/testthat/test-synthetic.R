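# The synthetic tract-lattice generator.

test_that("the lattice generator is deterministic and correctly sized", {
  lat <- simulateLattice(simConfig())
  expect_equal(nAreas(lat$graph), 96L)
  expect_true(isConnected(lat$graph))
  lat2x2 <- simulateLattice(simConfig(nx = 2, ny = 2))
  expect_equal(unname(nNeighbors(lat2x2$graph)), rep(3L, 4L))
  expect_identical(simulateLattice(simConfig())$graph@areaIds,
                   lat$graph@areaIds)
})

test_that("composition proportions are exact and symmetric when unforced", {
  g <- gridGraph(6, 6)
  comp <- simulateComposition(g, simConfig(nx = 6, ny = 6), seed = 2)
  shares <- as.matrix(comp[, c("white", "black", "asian", "hispanic")])
  expect_equal(rowSums(shares), rep(1, nrow(shares)), tolerance = 1e-12)
  # smoothing and polarisation off, equal baselines: group means near 1/4
  cfgSym <- simConfig(nx = 6, ny = 6, smoothingSteps = 0, polarization = 0,
                      baseline = c(white = 0, black = 0, asian = 0, hispanic = 0),
                      fieldScale = 1)
  means <- rowMeans(sapply(1:30, function(s) {
    colMeans(as.matrix(simulateComposition(g, cfgSym, seed = s)[,
      c("white", "black", "asian", "hispanic")]))
  }))
  expect_equal(unname(means), rep(0.25, 4), tolerance = 0.03)
})

test_that("the Black share is spatially autocorrelated at default smoothing", {
  nbCor <- sapply(1:50, function(s) {
    study <- simulateStudy(seed = s)
    bs <- study$composition$black
    el <- edgeList(study$graph)
    i <- match(el$id_a, areaIds(study$graph))
    j <- match(el$id_b, areaIds(study$graph))
    cor(bs[i], bs[j])
  })
  expect_gt(mean(nbCor), 0.3)
  expect_true(all(nbCor > 0))
})

test_that("SES covariates honour the configured race correlation", {
  g <- gridGraph(10, 10)
  cfg0 <- simConfig(nx = 10, ny = 10,
                    sesRaceCor = c(pctPoverty = 0, pctSnap = 0,
                                   pctNoVehicle = 0, pctVacant = 0,
                                   pctCollege = 0))
  cors <- sapply(1:30, function(s) {
    comp <- simulateComposition(g, cfg0, seed = s)
    ses <- simulateCovariates(comp, cfg0, seed = s + 1000)
    cor(comp$black, ses$pctPoverty)
  })
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)) + 0.02)
  # default config: positive correlation for poverty, negative for college
  study <- simulateStudy(seed = 6)
  expect_gt(cor(study$composition$black, study$areaTable$pctPoverty), 0.2)
  expect_lt(cor(study$composition$black, study$areaTable$pctCollege), -0.2)
  # percentages live in [0, 100]
  ses <- study$areaTable[, c("pctPoverty", "pctSnap", "pctNoVehicle",
                             "pctVacant", "pctCollege")]
  expect_true(all(ses >= 0 & ses <= 100))
})

test_that("the default design passes the VIF screen", {
  for (s in 1:10) {
    study <- simulateStudy(seed = s)
    v <- computeVif(designMatrix(study$areaTable, modelSpec(4)))
    expect_true(all(v$vif < 6), label = paste("seed", s))
  }
})

test_that("structural zeros appear at the configured rate", {
  # large lambda: Poisson zeros are negligible, so zeros ~ Binomial(n, pi0)
  cfg <- simConfig(trueBeta0 = 4, truePi0 = 0.3,
                   trueTauU = 1e8, trueTauV = 1e8, offsetRule = "none")
  zf <- sapply(1:30, function(s) {
    study <- simulateStudy(cfg, seed = s)
    mean(study$areaTable$storeCount == 0)
  })
  se <- sqrt(0.3 * 0.7 / 96)
  expect_lt(abs(mean(zf) - 0.3), 3 * se / sqrt(length(zf)))
})

test_that("with effects silenced the counts are plain Poisson", {
  cfg <- simConfig(trueBeta0 = log(2), truePi0 = 0,
                   trueTauU = 1e10, trueTauV = 1e10,
                   trueBeta = setNames(rep(0, 10), names(simConfig()$trueBeta)),
                   offsetRule = "none")
  ys <- unlist(lapply(1:20, function(s) simulateStudy(cfg, seed = s)$areaTable$storeCount))
  expect_equal(mean(ys), 2, tolerance = 0.05)
  expect_equal(var(ys), 2, tolerance = 0.1)   # Poisson mean-variance identity
})

test_that("the generator is reproducible and schema-consistent", {
  s1 <- simulateStudy(seed = 42)
  s2 <- simulateStudy(seed = 42)
  expect_identical(s1$areaTable, s2$areaTable)
  expect_identical(s1$truth, s2$truth)
  tab <- s1$areaTable
  expect_true(all(c("areaId", "storeCount", "population",
                    names(simConfig()$trueBeta)) %in% names(tab)))
  expect_true(all(tab$storeCount >= 0 & tab$storeCount == floor(tab$storeCount)))
  expect_true(all(tab$population > 0))
  expect_identical(tab$areaId, areaIds(s1$graph))
})

test_that("bundles round-trip through disk", {
  study <- simulateStudy(seed = 15)
  dir <- withr::local_tempdir()
  writeSyntheticBundle(study, dir)
  expect_true(all(file.exists(file.path(dir,
    c("area_table.csv", "composition.csv", "edges.csv",
      "geometry.geojson", "truth.json")))))
  tab <- readAreaTable(file.path(dir, "area_table.csv"))
  expect_equal(tab$storeCount, study$areaTable$storeCount)
  g <- areaGraphFromGeoJSON(file.path(dir, "geometry.geojson"))
  expect_identical(neighborList(g), neighborList(study$graph))
})
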