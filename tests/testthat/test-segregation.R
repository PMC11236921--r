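# Entropy segregation metrics, local G* clustering, VIF screening.

test_that("tract entropy hits its analytic values", {
  expect_equal(tractEntropy(c(1, 0, 0, 0)), 0)
  expect_equal(tractEntropy(rep(0.25, 4)), log(4))
  expect_equal(tractEntropy(c(0.5, 0.5, 0, 0)), log(2))
  expect_error(tractEntropy(c(0.5, 0.6)), "sum to 1")
  expect_error(tractEntropy(c(-0.1, 1.1)), "nonnegative")
})

test_that("tract entropy is permutation invariant and maximal at uniformity", {
  set.seed(1)
  for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    expect_equal(tractEntropy(p), tractEntropy(sample(p)))
    expect_lte(tractEntropy(p), log(4) + 1e-12)
  }
})

test_that("entropy deviation score has the documented endpoints", {
  city <- c(0.4, 0.4, 0.1, 0.1)
  expect_equal(entropyDeviationScore(city, city), 0)
  expect_equal(entropyDeviationScore(c(1, 0, 0, 0), city), 1)
  # a tract more diverse than the city clips to 0
  expect_equal(entropyDeviationScore(rep(0.25, 4), city), 0)
  expect_error(entropyDeviationScore(city, c(1, 0, 0, 0)), "single-group")
})

test_that("citywide entropy index matches a direct-summation oracle", {
  counts <- rbind(c(800, 100, 50, 50),
                  c(100, 700, 100, 100),
                  c(300, 300, 200, 200))
  pop <- rowSums(counts)
  # independent direct summation
  share <- counts / pop
  cityShare <- colSums(counts) / sum(counts)
  E <- -sum(cityShare * log(cityShare))
  Ei <- apply(share, 1, function(p) -sum(p[p > 0] * log(p[p > 0])))
  Hdirect <- sum(pop * (E - Ei)) / (E * sum(pop))
  expect_equal(citywideEntropyIndex(counts), Hdirect, tolerance = 1e-12)
})

test_that("citywide entropy index endpoints and bounds hold", {
  # every tract mirrors the city -> 0
  same <- rbind(c(400, 400, 100, 100), c(200, 200, 50, 50), c(800, 800, 200, 200))
  expect_equal(citywideEntropyIndex(same), 0, tolerance = 1e-12)
  # every tract single-group, city mixed -> 1
  single <- rbind(c(1000, 0, 0, 0), c(0, 500, 0, 0), c(0, 0, 300, 0), c(0, 0, 0, 200))
  expect_equal(citywideEntropyIndex(single), 1, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    counts <- matrix(rpois(20, 300), 5, 4)
    H <- citywideEntropyIndex(counts)
    expect_gte(H, 0); expect_lte(H, 1)
  }
  expect_warning(citywideEntropyIndex(rbind(c(10, 10), c(0, 0))), "zero-population")
  expect_error(citywideEntropyIndex(rbind(c(0, 0), c(0, 0))), "total population")
})

test_that("local G* matches the dense-formula oracle", {
  set.seed(11)
  for (i in 1:15) {
    g <- if (i %% 2 == 0) gridGraph(sample(3:5, 1), sample(3:5, 1)) else
      randomGraph(sample(5:25, 1))
    x <- rnorm(nAreas(g), sd = runif(1, 0.5, 3))
    expect_equal(unname(localGstar(x, g)), gstarDense(x, g), tolerance = 1e-10)
  }
})

test_that("a single hot cell lights up itself and its neighbours", {
  g <- gridGraph(5, 5)
  x <- rep(0, 25); x[13] <- 1          # centre of the 5x5 grid
  z <- localGstar(x, g)
  hot <- c("T013", neighborList(g)[["T013"]])
  expect_true(all(z[hot] > 0))
  far <- setdiff(areaIds(g), c(hot, unlist(neighborList(g)[hot])))
  expect_true(all(z[far] < 0))
})

test_that("degenerate constant surfaces give zero z-scores with a warning", {
  g <- gridGraph(3, 3)
  expect_warning(z <- localGstar(rep(2.5, 9), g), "constant")
  expect_equal(unname(z), rep(0, 9))
})

test_that("G* z-scores have near-zero mean for exchangeable inputs", {
  g <- gridGraph(5, 5)
  set.seed(99)
  m <- replicate(200, mean(localGstar(rnorm(25), g)))
  expect_lt(abs(mean(m)), 4 * sd(m) / sqrt(length(m)) + 0.02)
})

test_that("cluster classification follows the sign of z, ties to low", {
  z <- c(2.1, -0.5, 0)
  expect_equal(as.character(classifyClusters(z)), c("high", "low", "low"))
  expect_error(classifyClusters(c(1, NA)), "finite")
  # adding a constant to the surface leaves classes unchanged
  g <- gridGraph(4, 4)
  set.seed(2)
  x <- rnorm(16)
  expect_identical(classifyClusters(localGstar(x, g)),
                   classifyClusters(localGstar(x + 100, g)))
})

test_that("VIF matches the least-squares oracle and flags collinearity", {
  # mutually orthogonal, mean-centred columns -> all VIF exactly 1
  set.seed(3)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, 2:4]
  expect_equal(computeVif(X)$vif, rep(1, 3), tolerance = 1e-10)
  # duplicated column -> infinite VIF, flagged
  X2 <- cbind(a = rnorm(20), b = rnorm(20))
  X2 <- cbind(X2, c = X2[, "a"])
  v2 <- computeVif(X2)
  expect_true(is.infinite(v2$vif[v2$covariate == "a"]))
  expect_true(any(v2$flagged))
  # random 3-covariate design vs explicit lm() oracle
  set.seed(5)
  for (i in 1:10) {
    Z <- matrix(rnorm(90), 30, 3) %*% matrix(runif(9, -1, 1), 3, 3)
    colnames(Z) <- c("x1", "x2", "x3")
    v <- computeVif(Z)$vif
    oracle <- vapply(1:3, function(k) {
      r2 <- summary(lm(Z[, k] ~ Z[, -k]))$r.squared
      1 / (1 - r2)
    }, numeric(1))
    expect_equal(v, oracle, tolerance = 1e-10)
  }
  expect_error(computeVif(cbind(rnorm(10), rep(1, 10))), "zero-variance")
})

test_that("segregation feature table is keyed, bounded and consistent", {
  study <- simulateStudy(seed = 3)
  feats <- segregationFeatures(
    study$composition[, c("white", "black", "asian", "hispanic")],
    study$graph, population = study$composition$population)
  expect_identical(feats$areaId, areaIds(study$graph))
  expect_true(all(feats$entropyScore >= 0 & feats$entropyScore <= 1))
  expect_identical(as.character(feats$clusterBlack),
                   ifelse(feats$gstarZBlack > 0, "high", "low"))
  expect_identical(as.character(feats$clusterWhite),
                   ifelse(feats$gstarZWhite > 0, "high", "low"))
})
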