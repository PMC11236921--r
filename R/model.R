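## Model specification, priors, likelihood and log-posterior of the
## zero-inflated Poisson BYM regression.

.racialBlock <- c("entropyScore", "clusterBlack", "clusterWhite",
                  "pctAsian", "pctHispanic")
.sesBlock <- c("pctPoverty", "pctSnap", "pctNoVehicle",
               "pctVacant", "pctCollege")

#' Specify one of the four nested regression models
#'
#' Model 1 is the intercept-only baseline (spatial effects only); model 2
#' adds the racial-segregation block (entropy score, Black and White
#' cluster classes, percent Asian, percent Hispanic); model 3 the
#' socioeconomic block (percent below poverty, SNAP recipiency, no-vehicle
#' households, vacant housing, college-educated); model 4 is the full model
#' with both blocks.
#'
#' @param modelId integer 1-4.
#' @param racialBlock,sesBlock character vectors naming the covariate
#'   columns of each block (defaults match [segregationFeatures()] and the
#'   synthetic generator).
#' @param exceedanceThreshold threshold `c` for exceedance probabilities of
#'   the spatial-effect rate ratio `exp(u + v)`; default 1.
#' @param offsetRule one of `"population"` (`e_i = log(pop_i / mean(pop))`),
#'   `"log_population"`, or `"none"`.
#' @return a `ModelSpec` list with elements `modelId`, `covariates`,
#'   `exceedanceThreshold`, `offsetRule`.
#' @export
modelSpec <- function(modelId,
                      racialBlock = .racialBlock,
                      sesBlock = .sesBlock,
                      exceedanceThreshold = 1,
                      offsetRule = c("population", "log_population", "none")) {
  modelId <- as.integer(modelId)
  if (!modelId %in% 1:4) stop("modelId must be 1, 2, 3 or 4")
  if (exceedanceThreshold <= 0) stop("exceedanceThreshold must be positive")
  covariates <- switch(modelId,
    character(0),
    racialBlock,
    sesBlock,
    c(racialBlock, sesBlock)
  )
  structure(list(modelId = modelId, covariates = covariates,
                 exceedanceThreshold = exceedanceThreshold,
                 offsetRule = match.arg(offsetRule)),
            class = "ModelSpec")
}

#' Prior settings for the ZIP-BYM model
#'
#' Defaults follow the weakly-informative convention for this model family:
#' all regression coefficients (intercept included) get Normal priors with
#' mean 0 and precision 0.001 (variance 1000); the structured and
#' unstructured precisions `tau_u`, `tau_v` get Gamma(shape 1,
#' rate 0.00005) priors (equivalently a log-gamma law on the log
#' precision); the zero-inflation probability gets the era's standard
#' software default for the type-1 ZIP mixing weight, a Normal(mean -1,
#' precision 0.2) prior on the logit scale (prior median ~0.27 on the
#' probability scale). A very diffuse logit prior is deliberately avoided:
#' it is bathtub-shaped on the probability scale and drags a weakly
#' identified mixing weight to the boundary (see the methods vignette).
#'
#' @param betaMean,betaPrecision Normal prior on each coefficient.
#' @param tauShape,tauRate Gamma prior on each precision.
#' @param pi0Mean,pi0Precision Normal prior on `logit(pi0)`.
#' @return a `Priors` list.
#' @export
defaultPriors <- function(betaMean = 0, betaPrecision = 0.001,
                          tauShape = 1, tauRate = 0.00005,
                          pi0Mean = -1, pi0Precision = 0.2) {
  stopifnot(betaPrecision > 0, tauShape > 0, tauRate > 0, pi0Precision > 0)
  structure(list(betaMean = betaMean, betaPrecision = betaPrecision,
                 tauShape = tauShape, tauRate = tauRate,
                 pi0Mean = pi0Mean, pi0Precision = pi0Precision),
            class = "Priors")
}

#' Build the design matrix for a model specification
#'
#' Pulls the spec's covariate columns out of an area table, coding factor
#' columns (the cluster classes) as 0/1 dummies with the first level
#' ("low") as reference.
#'
#' @param data data.frame with one row per area.
#' @param spec a [modelSpec()].
#' @return numeric matrix (0 columns for model 1), with coefficient-ready
#'   column names.
#' @export
designMatrix <- function(data, spec) {
  if (!length(spec$covariates)) {
    return(matrix(numeric(0), nrow(data), 0L))
  }
  missing <- setdiff(spec$covariates, names(data))
  if (length(missing)) {
    stop("missing covariate column(s): ", paste(missing, collapse = ", "))
  }
  cols <- lapply(spec$covariates, function(nm) {
    v <- data[[nm]]
    if (is.factor(v) || is.character(v)) {
      f <- if (is.factor(v)) v else factor(v, levels = c("low", "high"))
      as.numeric(f == levels(f)[2L])
    } else {
      as.numeric(v)
    }
  })
  X <- do.call(cbind, cols)
  colnames(X) <- spec$covariates
  if (any(!is.finite(X))) stop("non-finite covariate values in design matrix")
  X
}

#' Offset vector under a model's offset rule
#'
#' @param population positive population per area.
#' @param rule see [modelSpec()].
#' @return numeric log-scale offset per area.
#' @export
offsetVector <- function(population, rule = "population") {
  if (any(population <= 0)) stop("population must be positive")
  switch(rule,
    population     = log(population / mean(population)),
    log_population = log(population),
    none           = rep(0, length(population)),
    stop("unknown offset rule '", rule, "'")
  )
}

#' Linear predictor of the log rate
#'
#' `log(lambda_i) = beta0 + sum_k beta_k x_ik + u_i + v_i + e_i`.
#'
#' @param beta coefficient vector, intercept first (length `ncol(X) + 1`).
#' @param covariates numeric design matrix `X` (0 columns allowed).
#' @param u,v spatial effect vectors per area.
#' @param offset log-scale offset `e` per area.
#' @return numeric log-rate vector.
#' @export
linearPredictor <- function(beta, covariates, u, v, offset) {
  X <- as.matrix(covariates)
  n <- nrow(X)
  if (length(beta) != ncol(X) + 1L) {
    stop("beta must have length ncol(covariates) + 1 (intercept first)")
  }
  if (length(u) != n || length(v) != n || length(offset) != n) {
    stop("u, v and offset must each have one value per area")
  }
  eta <- rep(beta[1L], n) + u + v + offset
  if (ncol(X)) eta <- eta + drop(X %*% beta[-1L])
  eta
}

#' Zero-inflated Poisson log-likelihood
#'
#' `sum_i log( pi0 * 1[y_i = 0] + (1 - pi0) * Poisson(y_i; lambda_i) )`,
#' computed on the log scale so that tiny mixture probabilities do not
#' underflow. With `pi0 = 0` this is exactly the Poisson log-likelihood.
#'
#' @param y nonnegative integer counts.
#' @param lambda positive Poisson rates (scalar or per-observation).
#' @param pi0 zero-inflation probability in \[0, 1\].
#' @return scalar log-likelihood.
#' @export
zipLoglik <- function(y, lambda, pi0) {
  if (any(y < 0) || any(y != floor(y))) stop("y must be nonnegative integers")
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (length(pi0) != 1L || pi0 < 0 || pi0 > 1) stop("pi0 must be a scalar in [0, 1]")
  lambda <- rep_len(lambda, length(y))
  lp <- dpois(y, lambda, log = TRUE)
  ll <- numeric(length(y))
  z <- y == 0
  if (pi0 == 0) {
    ll <- lp
  } else if (pi0 == 1) {
    if (any(!z)) return(-Inf)
    ll[] <- 0
  } else {
    ll[!z] <- log1p(-pi0) + lp[!z]
    # log( pi0 + (1-pi0) exp(lp) ), stable
    a <- log(pi0)
    b <- log1p(-pi0) + lp[z]
    m <- pmax(a, b)
    ll[z] <- m + log(exp(a - m) + exp(b - m))
  }
  sum(ll)
}

#' Joint log-posterior of the ZIP-BYM model (up to a constant)
#'
#' Sum of the ZIP log-likelihood, the ICAR term for `u` (including the
#' `rank/2 * log(tauU)` factor so that `tauU` inference is correct), iid
#' Normal terms for `v`, Normal priors on `beta`, Gamma priors on the
#' precisions, and a Normal prior on `logit(pi0)` (the mixture weight is
#' parameterised on the logit scale, so no Jacobian is applied). States
#' outside the support (`tau <= 0`, `pi0` outside (0,1)) return `-Inf`.
#'
#' @param state list with elements `beta`, `u`, `v`, `tauU`, `tauV`, `pi0`.
#' @param y counts per area.
#' @param covariates design matrix.
#' @param offset log-scale offset.
#' @param graph an [AreaGraph-class].
#' @param priors a [defaultPriors()] list.
#' @return scalar log-posterior up to an additive constant.
#' @export
logPosterior <- function(state, y, covariates, offset, graph,
                         priors = defaultPriors()) {
  if (!all(c("beta", "u", "v", "tauU", "tauV", "pi0") %in% names(state))) {
    stop("state must contain beta, u, v, tauU, tauV, pi0")
  }
  if (!is.finite(state$tauU) || state$tauU <= 0) return(-Inf)
  if (!is.finite(state$tauV) || state$tauV <= 0) return(-Inf)
  if (!is.finite(state$pi0) || state$pi0 <= 0 || state$pi0 >= 1) return(-Inf)
  eta <- linearPredictor(state$beta, covariates, state$u, state$v, offset)
  ll <- zipLoglik(y, exp(eta), state$pi0)
  lpU <- icarLogpdfUnnorm(state$u, graph, state$tauU) +
    (icarRank(graph) / 2) * log(state$tauU)
  lpV <- sum(dnorm(state$v, 0, sqrt(1 / state$tauV), log = TRUE))
  lpB <- sum(dnorm(state$beta, priors$betaMean,
                   sqrt(1 / priors$betaPrecision), log = TRUE))
  lpT <- dgamma(state$tauU, shape = priors$tauShape, rate = priors$tauRate, log = TRUE) +
    dgamma(state$tauV, shape = priors$tauShape, rate = priors$tauRate, log = TRUE)
  lpP <- dnorm(qlogis(state$pi0), priors$pi0Mean,
               sqrt(1 / priors$pi0Precision), log = TRUE)
  ll + lpU + lpV + lpB + lpT + lpP
}

#' Sampler settings
#'
#' Defaults are the reference run configuration: 4 chains of 20,000
#' iterations, the first 10,000 discarded, thin 1. Validation studies in
#' the package scale these down; the posterior summaries are insensitive to
#' that beyond Monte-Carlo error (see the methods vignette).
#'
#' @param nIter iterations per chain (including burn-in).
#' @param nBurn burn-in iterations discarded per chain.
#' @param nChains number of chains.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return a `SamplerSettings` list.
#' @export
samplerSettings <- function(nIter = 20000L, nBurn = 10000L,
                            nChains = 4L, thin = 1L) {
  stopifnot(nIter > nBurn, nBurn >= 0, nChains >= 1, thin >= 1)
  structure(list(nIter = as.integer(nIter), nBurn = as.integer(nBurn),
                 nChains = as.integer(nChains), thin = as.integer(thin)),
            class = "SamplerSettings")
}
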