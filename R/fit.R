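## MCMC fitting, posterior containers and summaries.

#' Fit the ZIP-BYM model by MCMC
#'
#' Metropolis-within-Gibbs: conjugate Gamma Gibbs updates for the two
#' precisions, latent structural-zero augmentation for the ZIP mixture,
#' and single-site random-walk Metropolis (scales adapted during burn-in)
#' for the coefficients, both spatial effect vectors and the logit of the
#' zero-inflation probability. The structured effect `u` is re-centred to
#' sum to zero each sweep, the global mean being absorbed into the
#' intercept. Continuous covariates are mean-centred internally for
#' sampling; reported intercept draws are mapped back to the original
#' covariate scale, so slopes and intercept are directly interpretable.
#'
#' A fixed `seed` reproduces the draws bit-for-bit. Chains are initialised
#' at `beta = 0`, `u = v = 0`, `tau = 1` and `pi0 = ` observed zero
#' fraction (floored at 0.01, capped at 0.95), with a small seed-dependent
#' jitter on the coefficients per chain.
#'
#' @param data data.frame with one row per area (aligned to `graph` id
#'   order) holding the count column `storeCount`, a `population` column,
#'   and the covariate columns named by `spec`.
#' @param graph an [AreaGraph-class].
#' @param spec a [modelSpec()].
#' @param priors a [defaultPriors()] list.
#' @param settings a [samplerSettings()] list.
#' @param seed integer seed.
#' @return a [ZipBymFit-class] with retained draws from all chains.
#' @export
fitMcmc <- function(data, graph, spec, priors = defaultPriors(),
                    settings = samplerSettings(), seed = 1L) {
  if (nrow(data) != nAreas(graph)) {
    stop("data has ", nrow(data), " rows but the graph has ",
         nAreas(graph), " areas")
  }
  if (!"storeCount" %in% names(data)) stop("data must contain 'storeCount'")
  if (!"population" %in% names(data)) stop("data must contain 'population'")
  y <- data$storeCount
  if (any(y < 0) || any(y != floor(y))) stop("storeCount must be nonnegative integers")
  X <- designMatrix(data, spec)
  offset <- offsetVector(data$population, spec$offsetRule)
  if (!isConnected(graph)) {
    warning("graph is disconnected: sum-to-zero is imposed per component, ",
            "and the intercept absorbs only the global mean of u")
  }
  deg <- nNeighbors(graph)
  island <- unname(deg == 0L)
  # centre continuous (non-dummy) covariates for the sampler
  xMeans <- rep(0, ncol(X))
  if (ncol(X)) {
    isDummy <- apply(X, 2L, function(col) all(col %in% c(0, 1)))
    xMeans[!isDummy] <- colMeans(X[, !isDummy, drop = FALSE])
  }
  Xc <- sweep(X, 2L, xMeans)
  pi0Init <- min(max(mean(y == 0), 0.01), 0.95)
  nb <- ncol(X) + 1L

  set.seed(as.integer(seed))
  chainSeeds <- sample.int(.Machine$integer.max - 1L, settings$nChains)
  res <- vector("list", settings$nChains)
  for (ch in seq_len(settings$nChains)) {
    set.seed(chainSeeds[ch])
    betaInit <- rnorm(nb, 0, 0.05)
    res[[ch]] <- .zipbymMcmcCpp(
      y = as.integer(y), X = Xc, offset = offset,
      adj = graph@adj, compId = graph@componentId, island = island,
      icarRank = icarRank(graph),
      nIter = settings$nIter, nBurn = settings$nBurn, thin = settings$thin,
      betaMean = priors$betaMean, betaPrec = priors$betaPrecision,
      tauShape = priors$tauShape, tauRate = priors$tauRate,
      pi0Mean = priors$pi0Mean, pi0Prec = priors$pi0Precision,
      betaInit = betaInit, pi0Init = pi0Init)
  }
  beta <- do.call(rbind, lapply(res, `[[`, "beta"))
  # uncentre the intercept: beta0_orig = beta0_centred - sum beta_k * xbar_k
  if (ncol(X)) beta[, 1L] <- beta[, 1L] - drop(beta[, -1L, drop = FALSE] %*% xMeans)
  colnames(beta) <- c("intercept", colnames(X))
  u <- do.call(rbind, lapply(res, `[[`, "u")); colnames(u) <- areaIds(graph)
  v <- do.call(rbind, lapply(res, `[[`, "v")); colnames(v) <- areaIds(graph)
  nKeep <- nrow(res[[1L]]$beta)
  fit <- new("ZipBymFit",
    beta = beta, u = u, v = v,
    tauU = unlist(lapply(res, `[[`, "tauU")),
    tauV = unlist(lapply(res, `[[`, "tauV")),
    pi0 = unlist(lapply(res, `[[`, "pi0")),
    chain = rep(seq_len(settings$nChains), each = nKeep),
    areaIds = areaIds(graph),
    settings = list(
      seed = as.integer(seed), chainSeeds = chainSeeds,
      sampler = settings, spec = spec, priors = priors,
      offset = offset, xMeans = xMeans,
      componentId = graph@componentId, island = island,
      acceptance = lapply(res, `[[`, "acceptance")))
  validObject(fit)
  fit
}

## ---- accessors -------------------------------------------------------------

#' @describeIn fitMcmc Coefficient draws (matrix, draws x coefficients).
#' @param fit a [ZipBymFit-class].
#' @export
betaDraws <- function(fit) fit@beta

#' @describeIn fitMcmc Structured spatial effect draws (draws x areas).
#' @export
uDraws <- function(fit) fit@u

#' @describeIn fitMcmc Unstructured effect draws (draws x areas).
#' @export
vDraws <- function(fit) fit@v

#' @describeIn fitMcmc Precision and zero-inflation draws as a data.frame.
#' @export
hyperDraws <- function(fit) {
  data.frame(tauU = fit@tauU, tauV = fit@tauV, pi0 = fit@pi0,
             chain = fit@chain)
}

#' @describeIn fitMcmc Number of retained draws across chains.
#' @export
nDraws <- function(fit) nrow(fit@beta)

setMethod("show", "ZipBymFit", function(object) {
  sp <- object@settings$spec
  cat("ZipBymFit: model", if (is.null(sp)) "?" else sp$modelId,
      "|", ncol(object@beta), "coefficient(s),",
      length(object@areaIds), "areas\n")
  cat("  ", nDraws(object), "retained draws from",
      length(unique(object@chain)), "chain(s), seed",
      object@settings$seed, "\n")
  s <- summarizePosterior(object)
  print(s$coefficients, digits = 3)
  invisible(NULL)
})

## ---- convergence diagnostics ----------------------------------------------

#' Split-chain R-hat and effective sample size
#'
#' Split-R-hat (each chain halved, between/within variance ratio) and a
#' basic autocorrelation-based effective sample size, computed per
#' parameter for the coefficients and hyperparameters.
#'
#' @param fit a [ZipBymFit-class].
#' @return data.frame with columns `parameter`, `rhat`, `ess`.
#' @export
convergenceDiagnostics <- function(fit) {
  mats <- cbind(fit@beta, tauU = fit@tauU, tauV = fit@tauV, pi0 = fit@pi0)
  out <- lapply(colnames(mats), function(nm) {
    data.frame(parameter = nm,
               rhat = .splitRhat(mats[, nm], fit@chain),
               ess = .essBasic(mats[, nm], fit@chain))
  })
  do.call(rbind, out)
}

.splitRhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    xi <- x[chain == ch]
    m <- length(xi) %/% 2L
    if (m < 2L) return(NA_real_)
    halves <- c(halves, list(xi[seq_len(m)], xi[m + seq_len(m)]))
  }
  m <- length(halves)
  nl <- lengths(halves)[1L]
  means <- vapply(halves, mean, numeric(1L))
  vars <- vapply(halves, var, numeric(1L))
  W <- mean(vars)
  B <- nl * var(means)
  if (W == 0) return(1)
  sqrt(((nl - 1) / nl * W + B / nl) / W)
}

.essBasic <- function(x, chain) {
  ess <- 0
  for (ch in unique(chain)) {
    xi <- x[chain == ch]
    nl <- length(xi)
    if (var(xi) == 0) { ess <- ess + nl; next }
    ac <- stats::acf(xi, lag.max = min(200L, nl - 1L), plot = FALSE)$acf[-1L]
    # sum positive-consecutive-pair autocorrelations (Geyer initial positive)
    s <- 0
    for (k in seq(1L, length(ac) - 1L, by = 2L)) {
      pair <- ac[k] + ac[k + 1L]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    ess <- ess + nl / (1 + 2 * s)
  }
  ess
}

## ---- posterior summaries ---------------------------------------------------

#' Summarise a fit as rate ratios with credible intervals
#'
#' For each coefficient: the posterior mean of `exp(beta)` (the rate
#' ratio), the central 95% credible interval (2.5 and 97.5 percentiles of
#' the `exp(beta)` draws), and a significance flag that is TRUE exactly
#' when 1 falls outside the interval. Hyperparameters (`tauU`, `tauV`,
#' `pi0`) are summarised on their own scale.
#'
#' @param fit a [ZipBymFit-class] with at least 100 retained draws.
#' @param level credible level (default 0.95).
#' @return list with `coefficients` (data.frame: `term`, `rr`, `ciLow`,
#'   `ciHigh`, `significant`) and `hyper` (data.frame: `parameter`, `mean`,
#'   `ciLow`, `ciHigh`).
#' @export
summarizePosterior <- function(fit, level = 0.95) {
  if (nDraws(fit) < 100L) {
    stop("need at least 100 retained draws, have ", nDraws(fit))
  }
  a <- (1 - level) / 2
  rrDraws <- exp(fit@beta)
  ci <- apply(rrDraws, 2L, quantile, probs = c(a, 1 - a), names = FALSE)
  coefs <- data.frame(
    term = colnames(fit@beta),
    rr = colMeans(rrDraws),
    ciLow = ci[1L, ],
    ciHigh = ci[2L, ],
    row.names = NULL
  )
  coefs$significant <- coefs$ciLow > 1 | coefs$ciHigh < 1
  hyp <- rbind(
    data.frame(parameter = "tauU", mean = mean(fit@tauU),
               t(quantile(fit@tauU, c(a, 1 - a), names = FALSE))),
    data.frame(parameter = "tauV", mean = mean(fit@tauV),
               t(quantile(fit@tauV, c(a, 1 - a), names = FALSE))),
    data.frame(parameter = "pi0", mean = mean(fit@pi0),
               t(quantile(fit@pi0, c(a, 1 - a), names = FALSE)))
  )
  names(hyp)[3:4] <- c("ciLow", "ciHigh")
  list(coefficients = coefs, hyper = hyp)
}

#' Percent change implied by a rate ratio
#'
#' `(rr - 1) * 100`, rounded to the nearest integer for reporting: an RR of
#' 0.87 is a 13% decrease, an RR of 1.92 a 92% increase.
#'
#' @param rr positive rate ratio(s).
#' @param digits rounding for the reported percentage (0 = nearest integer).
#' @return signed percentage(s).
#' @export
percentChange <- function(rr, digits = 0) {
  if (any(rr <= 0)) stop("rate ratios must be positive")
  round((rr - 1) * 100, digits)
}
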