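## DIC model comparison and exceedance-probability hotspot classification.

#' Deviance information criterion for a ZIP-BYM fit
#'
#' Conditional-deviance DIC: the deviance `D(theta) = -2 * zipLoglik` is
#' evaluated conditionally on the random effects at every retained draw,
#' giving the posterior mean deviance `Dbar`, and once at the plug-in
#' posterior means (`beta`, `u`, `v` averaged draw-wise; `pi0` averaged on
#' the logit scale), giving `Dhat`. Then `pD = Dbar - Dhat` and
#' `DIC = Dhat + 2 pD = Dbar + pD`. A negative `pD` (a known pathology of
#' conditional DIC under strong non-normality) is flagged with a warning,
#' not an error.
#'
#' @param fit a [ZipBymFit-class] with at least 100 retained draws.
#' @param data the area table the model was fitted to (`storeCount`,
#'   `population`, covariates).
#' @param spec the [modelSpec()] used for the fit; defaults to the one
#'   recorded in the fit.
#' @return named list `list(dic =, pD =, dBar =, dHat =)`.
#' @export
dic <- function(fit, data, spec = fit@settings$spec) {
  if (nDraws(fit) < 100L) stop("need at least 100 retained draws")
  y <- data$storeCount
  X <- designMatrix(data, spec)
  offset <- fit@settings$offset
  # draws x areas matrix of linear predictors
  Xfull <- cbind(intercept = 1, X)
  eta <- fit@beta %*% t(Xfull) + fit@u + fit@v +
    matrix(offset, nDraws(fit), length(y), byrow = TRUE)
  dev <- vapply(seq_len(nDraws(fit)), function(s) {
    -2 * zipLoglik(y, exp(eta[s, ]), fit@pi0[s])
  }, numeric(1L))
  dBar <- mean(dev)
  betaHat <- colMeans(fit@beta)
  uHat <- colMeans(fit@u)
  vHat <- colMeans(fit@v)
  pi0Hat <- plogis(mean(qlogis(fit@pi0)))
  etaHat <- linearPredictor(betaHat, X, uHat, vHat, offset)
  dHat <- -2 * zipLoglik(y, exp(etaHat), pi0Hat)
  if (!is.finite(dHat)) stop("non-finite deviance at the posterior mean")
  pD <- dBar - dHat
  if (pD < 0) warning("negative pD (", round(pD, 2), "): conditional-DIC pathology")
  list(dic = dHat + 2 * pD, pD = pD, dBar = dBar, dHat = dHat)
}

#' Rank candidate models by DIC
#'
#' The model with the smallest DIC is preferred. Evidence is graded
#' "substantial" when its lead over the runner-up is at least 3 DIC points
#' (the conventional 3-7 band for meaningful DIC differences), otherwise
#' "weak". Exact ties at the minimum yield no preferred model and a
#' warning.
#'
#' @param dics named numeric vector of DIC values (>= 2 models), or a list
#'   of [dic()] results.
#' @param pD optional named numeric vector of effective parameter counts to
#'   carry through to the report.
#' @return data.frame sorted ascending by DIC with columns `model`, `dic`,
#'   (`pD`,) `deltaDic`, `preferred`, `evidence`.
#' @export
compareModels <- function(dics, pD = NULL) {
  if (is.list(dics) && !is.null(dics[[1L]]$dic)) {
    if (is.null(pD)) pD <- vapply(dics, `[[`, numeric(1L), "pD")
    dics <- vapply(dics, `[[`, numeric(1L), "dic")
  }
  if (length(dics) < 2L) stop("need at least 2 models to compare")
  if (is.null(names(dics)) || any(!nzchar(names(dics)))) {
    names(dics) <- paste0("model", seq_along(dics))
  }
  ord <- order(dics)
  out <- data.frame(model = names(dics)[ord], dic = unname(dics[ord]),
                    row.names = NULL)
  if (!is.null(pD)) out$pD <- unname(pD[ord])
  out$deltaDic <- out$dic - out$dic[1L]
  tied <- sum(dics == min(dics)) > 1L
  out$preferred <- !tied & seq_len(nrow(out)) == 1L
  if (tied) warning("tie at the minimum DIC: no model preferred")
  runnerGap <- out$dic[2L] - out$dic[1L]
  out$evidence <- ifelse(out$preferred,
                         ifelse(runnerGap >= 3, "substantial", "weak"),
                         "")
  out
}

#' Posterior exceedance probabilities of the spatial-effect rate ratio
#'
#' For each area, the fraction of retained draws in which the combined
#' spatial effect exceeds the threshold on the rate-ratio scale:
#' `p_i = Pr(exp(u_i + v_i) > c | data)`. With the default `c = 1` this
#' asks where the model places stores above (or below) the citywide level
#' after the covariates are accounted for. Set `component = "structured"`
#' to use `exp(u)` alone.
#'
#' @param fit a [ZipBymFit-class].
#' @param threshold positive rate-ratio threshold `c` (default taken from
#'   the fit's model spec, itself defaulting to 1).
#' @param component `"combined"` (`u + v`, default) or `"structured"` (`u`).
#' @return data.frame keyed by `areaId` with columns `exceedanceProb`,
#'   `class` (factor: coldspot / neither / hotspot).
#' @export
exceedanceProbability <- function(fit,
                                  threshold = NULL,
                                  component = c("combined", "structured")) {
  component <- match.arg(component)
  if (is.null(threshold)) {
    threshold <- fit@settings$spec$exceedanceThreshold
    if (is.null(threshold)) threshold <- 1
  }
  if (threshold <= 0) stop("threshold must be positive")
  if (nDraws(fit) == 0L) stop("no retained draws")
  eff <- if (component == "combined") fit@u + fit@v else fit@u
  p <- colMeans(eff > log(threshold))
  data.frame(areaId = fit@areaIds, exceedanceProb = unname(p),
             class = classifyExceedance(unname(p)), row.names = NULL)
}

#' Hotspot / coldspot classification of exceedance probabilities
#'
#' Fixed cut-points: `p < 0.2` is a coldspot, `0.2 <= p < 0.8` is neither,
#' `p >= 0.8` is a hotspot (half-open boundary convention; the cut-points
#' are configurable).
#'
#' @param p exceedance probabilities in \[0, 1\].
#' @param cuts length-2 increasing vector of cut-points in (0, 1).
#' @return factor with levels `coldspot`, `neither`, `hotspot`.
#' @export
classifyExceedance <- function(p, cuts = c(0.2, 0.8)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("exceedance probabilities must lie in [0, 1]")
  }
  if (length(cuts) != 2L || cuts[1L] >= cuts[2L]) stop("cuts must be increasing, length 2")
  cls <- ifelse(p < cuts[1L], "coldspot", ifelse(p < cuts[2L], "neither", "hotspot"))
  factor(cls, levels = c("coldspot", "neither", "hotspot"))
}
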