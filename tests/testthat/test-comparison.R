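# DIC computation, model ranking and exceedance classification.

# build a ZipBymFit by hand from draw matrices (for DIC edge cases)
makeFit <- function(beta, u, v, tauU, tauV, pi0, graph, offset) {
  new("ZipBymFit", beta = beta, u = u, v = v,
      tauU = tauU, tauV = tauV, pi0 = pi0,
      chain = rep(1L, nrow(beta)), areaIds = areaIds(graph),
      settings = list(offset = offset, spec = modelSpec(1),
                      componentId = graph@componentId,
                      island = unname(nNeighbors(graph) == 0L)))
}

test_that("a degenerate posterior has pD = 0 and DIC = D(thetaHat)", {
  g <- gridGraph(4, 3)
  n <- nAreas(g)
  m <- 150
  beta <- matrix(0.4, m, 1, dimnames = list(NULL, "intercept"))
  u <- matrix(0, m, n); v <- matrix(0, m, n)
  fit <- makeFit(beta, u, v, rep(1, m), rep(1, m), rep(0.2, m), g, rep(0, n))
  d <- data.frame(areaId = areaIds(g), storeCount = rpois(n, 1.5),
                  population = 1000)
  res <- dic(fit, d)
  expect_equal(res$pD, 0, tolerance = 1e-10)
  expect_equal(res$dic, res$dHat, tolerance = 1e-10)
  expect_equal(res$dHat, -2 * zipLoglik(d$storeCount, rep(exp(0.4), n), 0.2))
})

test_that("pD approximates the free-parameter count in a Gaussian regime", {
  # Poisson intercept model with large counts: the posterior of beta0 is
  # asymptotically Normal(bHat, 1/sum(y)), and conditional-deviance pD for
  # one free parameter is ~1
  set.seed(23)
  g <- gridGraph(5, 4)
  n <- nAreas(g)
  y <- rpois(n, 50)
  bHat <- log(mean(y))
  m <- 4000
  beta <- matrix(rnorm(m, bHat, sqrt(1 / sum(y))), m, 1,
                 dimnames = list(NULL, "intercept"))
  fit <- makeFit(beta, matrix(0, m, n), matrix(0, m, n),
                 rep(1, m), rep(1, m), rep(1e-9, m), g, rep(0, n))
  d <- data.frame(areaId = areaIds(g), storeCount = y, population = 1000)
  res <- dic(fit, d)
  expect_equal(res$pD, 1, tolerance = 0.15)
})

test_that("adding a single null covariate barely moves the DIC", {
  set.seed(29)
  specNull <- modelSpec(2)
  specNull$covariates <- "pctPoverty"   # true effect is zero by default
  deltas <- replicate(10, {
    study <- simulateStudy(seed = sample.int(1e6, 1))
    f0 <- fitMcmc(study$areaTable, study$graph, modelSpec(1),
                  settings = testSettings(3000, 1500), seed = 3)
    f1 <- fitMcmc(study$areaTable, study$graph, specNull,
                  settings = testSettings(3000, 1500), seed = 3)
    dic(f1, study$areaTable)$dic - dic(f0, study$areaTable)$dic
  })
  expect_lt(abs(mean(deltas)), 2.5)
})

test_that("model ranking prefers the smallest DIC and grades evidence", {
  dics <- c(model1 = 481.87, model2 = 476.29, model3 = 484.90, model4 = 483.04)
  rep <- compareModels(dics)
  expect_equal(rep$model[1], "model2")
  expect_true(rep$preferred[1])
  expect_equal(rep$deltaDic[1], 0)
  expect_equal(sum(rep$preferred), 1L)
  expect_equal(rep$evidence[1], "substantial")  # gap 5.58 >= 3
  # a 1-point gap is preferred but weak
  rep2 <- compareModels(c(a = 100, b = 101))
  expect_equal(rep2$evidence[1], "weak")
  # exact ties yield no preference and a warning
  expect_warning(rep3 <- compareModels(c(a = 100, b = 100)), "tie")
  expect_false(any(rep3$preferred))
  expect_error(compareModels(c(a = 1)), "at least 2")
})

test_that("exceedance probabilities count draws above the threshold", {
  g <- gridGraph(3, 3)
  n <- nAreas(g)
  m <- 1000
  set.seed(31)
  u <- matrix(rnorm(m * n, 0, 0.5), m, n)
  u <- u - rowMeans(u)
  v <- matrix(rnorm(m * n, 0, 0.3), m, n)
  fit <- makeFit(matrix(0, m, 1, dimnames = list(NULL, "intercept")),
                 u, v, rep(1, m), rep(1, m), rep(0.1, m), g, rep(0, n))
  ex <- exceedanceProbability(fit, threshold = 1)
  # recount oracle straight from the draw matrices
  expect_identical(ex$exceedanceProb, unname(colMeans(u + v > 0)))
  # symmetric draws sit near 0.5
  expect_true(all(abs(ex$exceedanceProb - 0.5) < 0.1))
  # all-positive combined effect gives probability 1 (u stays centred)
  v2 <- abs(v) + max(abs(u)) + 0.01
  fit2 <- makeFit(matrix(0, m, 1, dimnames = list(NULL, "intercept")),
                  u, v2, rep(1, m), rep(1, m), rep(0.1, m),
                  g, rep(0, n))
  ex2 <- exceedanceProbability(fit2, threshold = 1)
  expect_equal(ex2$exceedanceProb, rep(1, n))
  # structured-only variant uses u alone
  exU <- exceedanceProbability(fit, threshold = 1, component = "structured")
  expect_identical(exU$exceedanceProb, unname(colMeans(u > 0)))
})

test_that("exceedance classification uses the fixed cut-points", {
  expect_equal(as.character(classifyExceedance(c(0.15, 0.50, 0.85))),
               c("coldspot", "neither", "hotspot"))
  # boundary convention: half-open at 0.2 and 0.8
  expect_equal(as.character(classifyExceedance(c(0.2, 0.8))),
               c("neither", "hotspot"))
  expect_error(classifyExceedance(1.2), "0, 1")
  # monotone: higher p never maps to a lower class
  p <- seq(0, 1, by = 0.01)
  cls <- as.integer(classifyExceedance(p))
  expect_true(all(diff(cls) >= 0))
})
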