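// Metropolis-within-Gibbs sampler for the zero-inflated Poisson BYM model.
//
// Parameterisation: log(lambda_i) = beta0 + x_i'beta + u_i + v_i + e_i,
// y_i ~ pi0 * delta_0 + (1 - pi0) * Poisson(lambda_i).
// A latent indicator z_i (structural zero) is sampled for every y_i = 0,
// which makes all count updates plain Poisson and the pi0 update binomial.
// tau_u and tau_v are conjugate Gamma Gibbs draws; beta, u, v and
// logit(pi0) are single-site random-walk Metropolis with burn-in scale
// adaptation. All randomness goes through R's RNG, so set.seed() on the R
// side gives bit-for-bit reproducible draws.

#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

static inline double rgamma_rate(double shape, double rate) {
  return R::rgamma(shape, 1.0 / rate);
}

// Poisson log-likelihood kernel at one site (constants in y dropped)
static inline double pois_kern(double y, double eta) {
  return y * eta - std::exp(eta);
}

// [[Rcpp::export(name = ".zipbymMcmcCpp")]]
List zipbym_mcmc_cpp(IntegerVector y, NumericMatrix X, NumericVector offset,
                     List adj, IntegerVector compId, LogicalVector island,
                     int icarRank,
                     int nIter, int nBurn, int thin,
                     double betaMean, double betaPrec,
                     double tauShape, double tauRate,
                     double pi0Mean, double pi0Prec,
                     NumericVector betaInit, double pi0Init) {
  const int n = y.size();
  const int p = X.ncol();          // covariates, intercept excluded
  const int nb = p + 1;            // coefficients including intercept

  // neighbour structure as plain vectors
  std::vector<std::vector<int> > nbrs(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    nbrs[i].assign(a.begin(), a.end());
    for (size_t k = 0; k < nbrs[i].size(); ++k) nbrs[i][k] -= 1; // 0-based
  }
  int nComp = 0, nNonIsland = 0;
  for (int i = 0; i < n; ++i) {
    if (!island[i]) ++nNonIsland;
    if (compId[i] > nComp) nComp = compId[i];
  }

  // state
  std::vector<double> beta(betaInit.begin(), betaInit.end());
  std::vector<double> u(n, 0.0), v(n, 0.0);
  double tauU = 1.0, tauV = 1.0;
  double lpi = std::log(pi0Init / (1.0 - pi0Init)); // logit(pi0)
  std::vector<int> z(n, 0);

  // cached linear predictor
  std::vector<double> eta(n);
  auto recomputeEta = [&]() {
    for (int i = 0; i < n; ++i) {
      double e = beta[0] + u[i] + v[i] + offset[i];
      for (int k = 0; k < p; ++k) e += X(i, k) * beta[k + 1];
      eta[i] = e;
    }
  };
  recomputeEta();

  // adaptive proposal scales
  std::vector<double> sBeta(nb, 0.1);
  double sU = 0.5, sV = 0.5, sPi = 1.0;
  std::vector<int> accBeta(nb, 0);
  int accU = 0, accV = 0, accPi = 0;
  int triesU = 0, triesV = 0, triesPi = 0;
  std::vector<int> triesBeta(nb, 0);
  const int adaptBatch = 50;
  // post-burn acceptance bookkeeping
  std::vector<long> keepAccBeta(nb, 0), keepTryBeta(nb, 0);
  long keepAccU = 0, keepTryU = 0, keepAccV = 0, keepTryV = 0;
  long keepAccPi = 0, keepTryPi = 0;

  const int nKeep = (nIter - nBurn) / thin;
  NumericMatrix outBeta(nKeep, nb), outU(nKeep, n), outV(nKeep, n);
  NumericVector outTauU(nKeep), outTauV(nKeep), outPi0(nKeep);

  RNGScope scope;
  int kept = 0;
  for (int iter = 0; iter < nIter; ++iter) {
    const bool burn = iter < nBurn;
    double pi0 = 1.0 / (1.0 + std::exp(-lpi));

    // --- latent structural-zero indicators -------------------------------
    int nz = 0;
    for (int i = 0; i < n; ++i) {
      if (y[i] > 0) { z[i] = 0; continue; }
      double lam = std::exp(eta[i]);
      double p1 = pi0 / (pi0 + (1.0 - pi0) * std::exp(-lam));
      z[i] = (unif_rand() < p1) ? 1 : 0;
      nz += z[i];
    }

    // --- pi0 on the logit scale ------------------------------------------
    {
      double prop = lpi + sPi * norm_rand();
      // binomial likelihood in z + Normal prior on the logit
      double cur = nz * (-std::log1p(std::exp(-lpi)))
                 + (n - nz) * (-std::log1p(std::exp(lpi)))
                 - 0.5 * pi0Prec * (lpi - pi0Mean) * (lpi - pi0Mean);
      double nw  = nz * (-std::log1p(std::exp(-prop)))
                 + (n - nz) * (-std::log1p(std::exp(prop)))
                 - 0.5 * pi0Prec * (prop - pi0Mean) * (prop - pi0Mean);
      if (std::log(unif_rand()) < nw - cur) {
        lpi = prop; ++accPi; if (!burn) ++keepAccPi;
      }
      ++triesPi; if (!burn) ++keepTryPi;
    }

    // --- regression coefficients (single-site RWM) ------------------------
    for (int k = 0; k < nb; ++k) {
      double d = sBeta[k] * norm_rand();
      double dll = 0.0;
      bool ok = true;
      for (int i = 0; i < n; ++i) {
        if (z[i]) continue;
        double xk = (k == 0) ? 1.0 : X(i, k - 1);
        if (xk == 0.0) continue;
        double en = eta[i] + xk * d;
        if (en > 700.0) { ok = false; break; }
        dll += pois_kern((double) y[i], en) - pois_kern((double) y[i], eta[i]);
      }
      double bNew = beta[k] + d;
      double dpr = -0.5 * betaPrec *
        ((bNew - betaMean) * (bNew - betaMean) -
         (beta[k] - betaMean) * (beta[k] - betaMean));
      if (ok && std::log(unif_rand()) < dll + dpr) {
        beta[k] = bNew;
        for (int i = 0; i < n; ++i) {
          double xk = (k == 0) ? 1.0 : X(i, k - 1);
          eta[i] += xk * d;
        }
        ++accBeta[k]; if (!burn) ++keepAccBeta[k];
      }
      ++triesBeta[k]; if (!burn) ++keepTryBeta[k];
    }

    // --- structured effect u (single-site RWM, islands fixed at 0) --------
    for (int i = 0; i < n; ++i) {
      if (island[i]) continue;
      double d = sU * norm_rand();
      double uNew = u[i] + d;
      double en = eta[i] + d;
      if (en > 700.0) { ++triesU; if (!burn) ++keepTryU; continue; }
      double dll = z[i] ? 0.0
        : pois_kern((double) y[i], en) - pois_kern((double) y[i], eta[i]);
      double dpr = 0.0;
      for (size_t s = 0; s < nbrs[i].size(); ++s) {
        double uj = u[nbrs[i][s]];
        dpr += (uNew - uj) * (uNew - uj) - (u[i] - uj) * (u[i] - uj);
      }
      dpr *= -0.5 * tauU;
      if (std::log(unif_rand()) < dll + dpr) {
        u[i] = uNew; eta[i] = en; ++accU; if (!burn) ++keepAccU;
      }
      ++triesU; if (!burn) ++keepTryU;
    }

    // recentre u to sum-to-zero per component; the global mean is absorbed
    // into the intercept (exact for a connected graph)
    {
      std::vector<double> cm(nComp + 1, 0.0);
      std::vector<int> cn(nComp + 1, 0);
      for (int i = 0; i < n; ++i) {
        if (island[i]) continue;
        cm[compId[i]] += u[i]; cn[compId[i]] += 1;
      }
      double gsum = 0.0;
      for (int c = 1; c <= nComp; ++c) {
        if (cn[c] > 0) { gsum += cm[c]; cm[c] /= cn[c]; }
      }
      double gmean = (nNonIsland > 0) ? gsum / nNonIsland : 0.0;
      for (int i = 0; i < n; ++i) {
        if (!island[i]) u[i] -= cm[compId[i]];
      }
      beta[0] += gmean;
      recomputeEta();
    }

    // --- unstructured effect v (single-site RWM) --------------------------
    for (int i = 0; i < n; ++i) {
      double d = sV * norm_rand();
      double vNew = v[i] + d;
      double en = eta[i] + d;
      if (en > 700.0) { ++triesV; if (!burn) ++keepTryV; continue; }
      double dll = z[i] ? 0.0
        : pois_kern((double) y[i], en) - pois_kern((double) y[i], eta[i]);
      double dpr = -0.5 * tauV * (vNew * vNew - v[i] * v[i]);
      if (std::log(unif_rand()) < dll + dpr) {
        v[i] = vNew; eta[i] = en; ++accV; if (!burn) ++keepAccV;
      }
      ++triesV; if (!burn) ++keepTryV;
    }

    // --- conjugate precision updates --------------------------------------
    {
      double energy = 0.0;
      for (int i = 0; i < n; ++i) {
        for (size_t s = 0; s < nbrs[i].size(); ++s) {
          int j = nbrs[i][s];
          if (j > i) energy += (u[i] - u[j]) * (u[i] - u[j]);
        }
      }
      tauU = rgamma_rate(tauShape + 0.5 * icarRank, tauRate + 0.5 * energy);
      double ssv = 0.0;
      for (int i = 0; i < n; ++i) ssv += v[i] * v[i];
      tauV = rgamma_rate(tauShape + 0.5 * n, tauRate + 0.5 * ssv);
    }

    // --- burn-in scale adaptation (Robbins-Monro toward 0.44) --------------
    if (burn && ((iter + 1) % adaptBatch == 0)) {
      double step = std::min(0.1, 1.0 / std::sqrt((iter + 1.0) / adaptBatch));
      for (int k = 0; k < nb; ++k) {
        double rate = triesBeta[k] > 0 ? (double) accBeta[k] / triesBeta[k] : 0.44;
        sBeta[k] *= std::exp(rate > 0.44 ? step : -step);
        accBeta[k] = 0; triesBeta[k] = 0;
      }
      double rU = triesU > 0 ? (double) accU / triesU : 0.44;
      sU *= std::exp(rU > 0.44 ? step : -step); accU = 0; triesU = 0;
      double rV = triesV > 0 ? (double) accV / triesV : 0.44;
      sV *= std::exp(rV > 0.44 ? step : -step); accV = 0; triesV = 0;
      double rP = triesPi > 0 ? (double) accPi / triesPi : 0.44;
      sPi *= std::exp(rP > 0.44 ? step : -step); accPi = 0; triesPi = 0;
    }

    // --- store -------------------------------------------------------------
    if (!burn && ((iter - nBurn) % thin == 0) && kept < nKeep) {
      for (int k = 0; k < nb; ++k) outBeta(kept, k) = beta[k];
      for (int i = 0; i < n; ++i) { outU(kept, i) = u[i]; outV(kept, i) = v[i]; }
      outTauU[kept] = tauU;
      outTauV[kept] = tauV;
      outPi0[kept] = 1.0 / (1.0 + std::exp(-lpi));
      ++kept;
    }
  }

  NumericVector accRates = NumericVector::create(
    _["beta"] = keepTryBeta[0] > 0 ?
      std::accumulate(keepAccBeta.begin(), keepAccBeta.end(), 0.0) /
      std::accumulate(keepTryBeta.begin(), keepTryBeta.end(), 0.0) : NA_REAL,
    _["u"]   = keepTryU > 0 ? (double) keepAccU / keepTryU : NA_REAL,
    _["v"]   = keepTryV > 0 ? (double) keepAccV / keepTryV : NA_REAL,
    _["pi0"] = keepTryPi > 0 ? (double) keepAccPi / keepTryPi : NA_REAL);

  return List::create(
    _["beta"] = outBeta, _["u"] = outU, _["v"] = outV,
    _["tauU"] = outTauU, _["tauV"] = outTauV, _["pi0"] = outPi0,
    _["acceptance"] = accRates);
}

// The exact Gibbs draw used for tau_u / tau_v inside the sampler, exposed
// so its distribution can be checked against the closed-form Gamma
// conditional.
// [[Rcpp::export(name = ".drawTauConditionalCpp")]]
NumericVector draw_tau_conditional_cpp(int nDraws, double shape, double rate) {
  RNGScope scope;
  NumericVector out(nDraws);
  for (int i = 0; i < nDraws; ++i) out[i] = rgamma_rate(shape, rate);
  return out;
}
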