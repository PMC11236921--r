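# Model specification, likelihood and log-posterior.

test_that("model specs carry the documented covariate blocks", {
  expect_length(modelSpec(1)$covariates, 0)
  expect_equal(modelSpec(2)$covariates,
               c("entropyScore", "clusterBlack", "clusterWhite",
                 "pctAsian", "pctHispanic"))
  expect_equal(modelSpec(3)$covariates,
               c("pctPoverty", "pctSnap", "pctNoVehicle",
                 "pctVacant", "pctCollege"))
  expect_equal(modelSpec(4)$covariates,
               union(modelSpec(2)$covariates, modelSpec(3)$covariates))
  expect_error(modelSpec(5), "1, 2, 3 or 4")
})

test_that("the design matrix codes cluster factors with low as reference", {
  d <- data.frame(entropyScore = c(0.1, 0.9),
                  clusterBlack = factor(c("low", "high"), c("low", "high")),
                  clusterWhite = c("high", "low"),
                  pctAsian = c(1, 2), pctHispanic = c(3, 4))
  X <- designMatrix(d, modelSpec(2))
  expect_equal(unname(X[, "clusterBlack"]), c(0, 1))
  expect_equal(unname(X[, "clusterWhite"]), c(1, 0))
  expect_error(designMatrix(d[, -2], modelSpec(2)), "clusterBlack")
})

test_that("linear predictor composes its terms and validates dimensions", {
  n <- 5
  X <- matrix(rnorm(n * 2), n, 2)
  expect_equal(linearPredictor(c(0, 0, 0), X, rep(0, n), rep(0, n), rep(0, n)),
               rep(0, n))
  expect_equal(exp(linearPredictor(log(2), matrix(numeric(0), n, 0),
                                   rep(0, n), rep(0, n), rep(0, n))),
               rep(2, n))
  set.seed(8)
  beta <- rnorm(3); u <- rnorm(n); v <- rnorm(n); off <- rnorm(n)
  direct <- beta[1] + X[, 1] * beta[2] + X[, 2] * beta[3] + u + v + off
  expect_equal(linearPredictor(beta, X, u, v, off), direct, tolerance = 1e-12)
  expect_error(linearPredictor(beta, X, u[-1], v, off), "one value per area")
})

test_that("ZIP log-likelihood degenerates and evaluates exactly", {
  set.seed(12)
  y <- rpois(30, 2)
  lam <- exp(rnorm(30))
  expect_identical(zipLoglik(y, lam, 0), sum(dpois(y, lam, log = TRUE)))
  expect_equal(zipLoglik(0L, 3, 1), 0)
  expect_equal(zipLoglik(2L, 1.5, 0.3), log(0.7 * exp(-1.5) * 1.5^2 / 2))
  expect_error(zipLoglik(c(1, -1), 1, 0.1), "nonnegative")
  expect_error(zipLoglik(1L, 0, 0.1), "positive")
  expect_error(zipLoglik(1L, 1, 1.2), "pi0")
})

test_that("ZIP log-likelihood is stable for extreme rates", {
  expect_true(is.finite(zipLoglik(0L, 500, 0.2)))   # Poisson(0; 500) underflows
  expect_equal(zipLoglik(0L, 500, 0.2), log(0.2), tolerance = 1e-12)
})

test_that("log-posterior decomposes additively between states", {
  set.seed(21)
  g <- gridGraph(3, 3)
  n <- 9
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  y <- rpois(n, 2)
  off <- rnorm(n, 0, 0.2)
  pr <- defaultPriors()
  mk <- function() list(beta = rnorm(2), u = rnorm(n), v = rnorm(n),
                        tauU = runif(1, 0.5, 3), tauV = runif(1, 0.5, 3),
                        pi0 = runif(1, 0.05, 0.6))
  s1 <- mk(); s2 <- mk()
  lp <- function(s) logPosterior(s, y, X, off, g, pr)
  comp <- function(s) {
    eta <- linearPredictor(s$beta, X, s$u, s$v, off)
    c(lik = zipLoglik(y, exp(eta), s$pi0),
      u = icarLogpdfUnnorm(s$u, g, s$tauU) + icarRank(g) / 2 * log(s$tauU),
      v = sum(dnorm(s$v, 0, sqrt(1 / s$tauV), log = TRUE)),
      beta = sum(dnorm(s$beta, 0, sqrt(1 / pr$betaPrecision), log = TRUE)),
      tau = dgamma(s$tauU, pr$tauShape, rate = pr$tauRate, log = TRUE) +
        dgamma(s$tauV, pr$tauShape, rate = pr$tauRate, log = TRUE),
      pi0 = dnorm(qlogis(s$pi0), pr$pi0Mean, sqrt(1 / pr$pi0Precision), log = TRUE))
  }
  expect_equal(lp(s1) - lp(s2), sum(comp(s1)) - sum(comp(s2)), tolerance = 1e-10)
})

test_that("log-posterior beta gradient matches finite differences", {
  set.seed(31)
  g <- gridGraph(3, 3)
  n <- 9
  X <- matrix(numeric(0), n, 0)
  y <- rpois(n, 2)
  s <- list(beta = 0.3, u = rep(0, n), v = rep(0, n),
            tauU = 1, tauV = 1, pi0 = 0.2)
  h <- 1e-6
  sp <- s; sp$beta <- s$beta + h
  sm <- s; sm$beta <- s$beta - h
  num <- (logPosterior(sp, y, X, rep(0, n), g) -
          logPosterior(sm, y, X, rep(0, n), g)) / (2 * h)
  # analytic: d/db [ sum over i of ZIP terms ] + prior
  lam <- exp(s$beta)
  p0 <- s$pi0
  dll <- sum(ifelse(y == 0,
                    -(1 - p0) * exp(-lam) * lam / (p0 + (1 - p0) * exp(-lam)),
                    y - lam))
  ana <- dll - defaultPriors()$betaPrecision * s$beta
  expect_equal(num, ana, tolerance = 1e-5)
})

test_that("likelihood is invariant under the u/intercept translation", {
  set.seed(41)
  g <- gridGraph(3, 3)
  n <- 9
  X <- matrix(numeric(0), n, 0)
  y <- rpois(n, 2)
  off <- rnorm(n, 0, 0.1)
  s <- list(beta = 0.5, u = rnorm(n), v = rnorm(n), tauU = 2, tauV = 2, pi0 = 0.2)
  s2 <- s; s2$u <- s$u + 0.7; s2$beta <- s$beta - 0.7
  eta1 <- linearPredictor(s$beta, X, s$u, s$v, off)
  eta2 <- linearPredictor(s2$beta, X, s2$u, s2$v, off)
  expect_equal(eta1, eta2, tolerance = 1e-12)
  # the posterior difference is purely the beta-prior difference (ICAR term
  # is translation invariant)
  dPost <- logPosterior(s2, y, X, off, g) - logPosterior(s, y, X, off, g)
  dPrior <- dnorm(s2$beta, 0, sqrt(1000), log = TRUE) -
    dnorm(s$beta, 0, sqrt(1000), log = TRUE)
  expect_lt(abs(dPost - dPrior), 1e-10)
})

test_that("log-posterior is -Inf off the support", {
  g <- gridGraph(2, 2)
  base <- list(beta = 0, u = rep(0, 4), v = rep(0, 4), tauU = 1, tauV = 1, pi0 = 0.2)
  y <- c(0L, 1L, 2L, 0L)
  X <- matrix(numeric(0), 4, 0)
  lp <- function(s) logPosterior(s, y, X, rep(0, 4), g)
  expect_true(is.finite(lp(base)))
  expect_identical(lp(modifyList(base, list(tauU = -1))), -Inf)
  expect_identical(lp(modifyList(base, list(tauV = 0))), -Inf)
  expect_identical(lp(modifyList(base, list(pi0 = 1))), -Inf)
})

test_that("percent change reproduces reporting conventions", {
  expect_equal(percentChange(0.87), -13)
  expect_equal(percentChange(1.92), 92)
  expect_equal(percentChange(1.0), 0)
  expect_error(percentChange(0), "positive")
})
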