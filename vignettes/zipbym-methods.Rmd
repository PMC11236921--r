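---
title: "Methods: zero-inflated Poisson BYM regression for areal store counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zero-inflated Poisson BYM regression for areal store counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipbym)
```

# The problem

Food-store access varies sharply across the neighbourhoods of segregated
US cities. `zipbym` implements a Bayesian spatial workflow for asking, at
census-tract resolution, whether racial segregation or socioeconomic
deprivation better predicts where supermarkets and grocery stores sit:
tract-level segregation metrics, a family of four nested zero-inflated
Poisson regressions with spatially structured random effects, model
comparison by the deviance information criterion (DIC), and
exceedance-probability hotspot maps. Because the underlying store audits
and census extracts are not redistributable, the package ships a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, and every claim the package makes about itself is
validated against that generator.

# Segregation metrics

**Tract diversity and the entropy score.** For group shares
$p_1,\dots,p_R$ (here $R = 4$: White, Black, Asian, Hispanic), tract
diversity is the Shannon entropy $E_i = -\sum_r p_{ir}\ln p_{ir}$,
maximal at $\ln R$ for an even mix. The tract-level covariate used in the
regressions is the *deviation score*

$$h_i = \max\!\left(0,\; \frac{E - E_i}{E}\right),$$

where $E$ is the entropy of the citywide composition: 0 for a tract at
least as diverse as the city, 1 for a single-group tract. Natural
logarithms are used throughout; $h_i$ and the citywide index are
base-invariant because the base cancels in the ratio. Tracts *more*
diverse than the city are clipped to 0 — the score is a segregation
measure with the documented 0–1 endpoints, not a signed deviation. An
alternative tract-level reading (normalised diversity $1 - E_i/\ln R$)
exists; the deviation score is implemented because it is the only
tract-level quantity with the stated endpoints (identical composition
$\to$ 0, single group $\to$ 1).

**Citywide index.** The multigroup entropy index (Theil's H)
$$H = \sum_i \frac{t_i\,(E - E_i)}{E\,T}$$
weights each tract's (unclipped) deviation by its population $t_i$;
$H \in [0,1]$ with 0 = every tract mirrors the city and 1 = every tract
single-group. Zero-population tracts carry no information about residential
sorting and are dropped with a warning.

**Local clustering.** Concentrations of the Black and White shares are
scored with the Getis–Ord local $G_i^*$ statistic under binary queen
contiguity weights including self ($w_{ii} = 1$):

$$z_i = \frac{\sum_j w_{ij}x_j - \bar x W_i}
{S\sqrt{\left(n W_i - W_i^2\right)/(n-1)}},\qquad
W_i = \sum_j w_{ij},\; S = \sqrt{\tfrac1n\sum_j x_j^2 - \bar x^2}.$$

A tract is a *high* cluster when $z_i > 0$ and *low* otherwise; $z = 0$
ties break to low because strictly positive z is the stated high rule.
The weight scheme (binary contiguity, self included, population sd in the
denominator) is the classic starred variant; no permutation inference is
attempted — the z-scores only feed the binary cluster covariates.

**Collinearity screen.** Before fitting, the full covariate set is
screened with variance inflation factors, $VIF_k = 1/(1 - R_k^2)$ from
regressing covariate $k$ on the rest with intercept; values at or above 6
are flagged (warning, not abort, mirroring a screen-then-proceed
workflow). Exactly collinear columns report `Inf`.

# The regression model

For tract $i$ with store count $y_i$,

$$y_i \sim \pi_0\,\delta_0 + (1-\pi_0)\,\text{Poisson}(\lambda_i),\qquad
\log \lambda_i = \beta_0 + \sum_k \beta_k x_{ik} + u_i + v_i + e_i.$$

* $u$ is the spatially *structured* effect, an intrinsic CAR (Besag)
  field on the queen-contiguity graph: up to a constant,
  $\log p(u \mid \tau_u) = -\tfrac{\tau_u}{2}\sum_{i\sim j}(u_i-u_j)^2$,
  summed over unordered neighbour pairs (equal to the Laplacian quadratic
  form $u^\top (D-A)\, u$). The prior is improper — invariant to
  translating $u$ within a connected component — so $u$ is constrained to
  sum to zero per component. The proper part of the density carries a
  $\tfrac{\operatorname{rank}(D-A)}{2}\log\tau_u$ factor, which the
  package adds wherever $\tau_u$ itself is inferred.
* $v_i \overset{iid}\sim N(0, 1/\tau_v)$ is the unstructured
  heterogeneity; together $u + v$ is the BYM convolution.
* $e_i$ is a fixed log-exposure offset. The default is
  $e_i = \log(\text{pop}_i / \overline{\text{pop}})$, a population-based
  exposure standardisation; `log_population` and `none` are available.
* $\pi_0$ is a single shared structural-zero probability (type-1 ZIP, no
  covariates on the zero process).

**Priors.** Coefficients (intercept included) get $N(0, \sigma^2 = 1000)$
— i.e. mean 0, precision 0.001. The precisions get
$\tau_u, \tau_v \sim \text{Gamma}(\text{shape}=1, \text{rate}=5\times10^{-5})$,
the parameterisation in which the log-precision has a log-gamma law; this
prior has mean 20,000, so with weak data the spatial effects shrink hard
toward zero — a deliberate property of this well-known default, worth
keeping in mind when reading $\tau$ posteriors. The mixing weight is
parameterised on the logit scale with a $N(-1, 1/0.2)$ prior, the
standard software default for type-1 ZIP likelihoods of this model
family's era. A genuinely diffuse logit prior (e.g. precision 0.001) is
*not* used: on the probability scale it is bathtub-shaped and, when
$\pi_0$ is weakly identified (small counts, many Poisson zeros), it drags
the posterior to the boundary and distorts the covariate effects that
must then absorb the excess zeros.

**Four nested models.** Model 1: intercept + spatial effects only.
Model 2 adds the racial-segregation block (entropy score, Black and White
cluster classes coded 0/1 with low as reference, percent Asian, percent
Hispanic). Model 3 instead adds the socioeconomic block (percent below
poverty, SNAP recipiency, no-vehicle households, vacant housing,
college-educated). Model 4 includes both blocks.

# Inference

Sampling is Metropolis-within-Gibbs, implemented in C++:

1. latent structural-zero indicators $z_i \mid \cdot$ (exact Bernoulli)
   for every $y_i = 0$, which reduces all count updates to plain Poisson
   likelihoods and the $\pi_0$ update to a binomial one;
2. $\operatorname{logit}\pi_0$, each $\beta_k$, each $u_i$ and each $v_i$
   by single-site random-walk Metropolis, proposal scales adapted toward
   44% acceptance during burn-in only (Robbins–Monro batches of 50), so
   the post-burn-in kernel is fixed and valid;
3. $\tau_u \mid u \sim \text{Gamma}(1 + \tfrac{\text{rank}}2,\;
   5\times10^{-5} + \tfrac12\sum_{i\sim j}(u_i-u_j)^2)$ and
   $\tau_v \mid v \sim \text{Gamma}(1 + \tfrac n2,\;
   5\times10^{-5} + \tfrac12\sum_i v_i^2)$, exact conjugate draws;
4. $u$ re-centred to sum-to-zero per connected component each sweep, with
   the global mean absorbed into $\beta_0$ (exact for connected graphs;
   disconnected inputs warn, and the shipped lattices are connected).
   Islands (degree-0 areas) keep $u_i = 0$ and contribute nothing to the
   ICAR energy, which is undefined for them.

Continuous covariates are mean-centred internally for sampling and the
intercept draws are mapped back, so reported coefficients refer to the
original covariate scales. Initial values are $\beta = 0$ (plus a small
seed-dependent jitter per chain), $u = v = 0$, $\tau = 1$, $\pi_0$ at the
observed zero fraction floored at 0.01. All randomness flows through R's
RNG from a single seed: a fixed seed reproduces draws bit-for-bit. The
reference run configuration is 4 chains of 20,000 iterations with the
first half discarded; split-$\widehat R$ and an autocorrelation-based
effective sample size are reported per parameter.

**Summaries.** Each coefficient is reported as a rate ratio: the
posterior mean of $e^\beta$ with the central 95% interval of the
$e^\beta$ draws, flagged significant exactly when 1 falls outside the
interval, plus the `(RR - 1) x 100` percent-change phrasing used in
reports.

# Model comparison and hotspots

DIC uses the *conditional* deviance focus (the common convention of this
model family's software): $D(\theta) = -2\log p(y \mid \beta, u, v,
\pi_0)$, $\bar D$ averaged over retained draws, $D(\bar\theta)$ at the
posterior means ($\pi_0$ averaged on the logit scale), $p_D = \bar D -
D(\bar\theta)$ and $DIC = D(\bar\theta) + 2p_D$. Negative $p_D$ — a known
pathology of conditional DIC — is flagged with a warning rather than an
error. The model with the smallest DIC is preferred; the preference is
graded *substantial* only when the runner-up trails by at least 3 points,
the conventional lower edge of the 3–7 evidence band. Exact ties yield no
preference.

Hotspots are classified from the posterior exceedance probability of the
*combined* spatial effect on the rate-ratio scale,
$p_i = \Pr(e^{u_i + v_i} > c \mid y)$ with threshold $c = 1$: after the
covariates are accounted for, where does the model still place more
stores than the citywide level? Cut-points are half-open:
$p < 0.2$ coldspot, $0.2 \le p < 0.8$ neither, $p \ge 0.8$ hotspot; the
boundary convention and the cut-points are configurable, as is using the
structured effect $e^{u}$ alone.

# The synthetic study design

`simulateStudy()` generates the conditions every validation claim refers
to: a 12×8 lattice of unit-square tracts (96 areas, queen contiguity,
connected), with

* **Composition:** each group's latent score is a softmax baseline plus a
  smoothed Gaussian field on the graph; two partially correlated
  polarisation fields (correlation 0.3) push White and Black scores in
  opposite directions, producing contiguous White-majority and
  Black-majority regions that are not exact mirror images — as in real
  cities, where the two clustering maps overlap imperfectly. Baselines
  give citywide shares of roughly 39/44/6/11 percent (White / Black /
  Asian / Hispanic), the profile of a strongly segregated mid-size US
  city. One neighbour-averaging pass of smoothing leaves the Black share
  clearly autocorrelated (neighbour correlation ≈ 0.6) while keeping
  tract-to-tract texture.
* **SES covariates:** five percentage-scale covariates, each a linear
  function of the standardised Black share plus noise (correlations 0.45
  to 0.6, negative for college education), scaled to the means and
  standard deviations typical of a high-poverty city (e.g. poverty
  36 ± 15%), clipped to [0, 100]. At the default settings the generated
  design passes the VIF < 6 screen; the cluster covariates sit around
  VIF 3–5, close to the values such screens report on real tract data.
* **Counts:** $u$ drawn exactly from the ICAR law (eigen-decomposition of
  the Laplacian restricted to its non-null space, sum-to-zero per
  component) with $\tau_u = 10$, $v$ iid with $\tau_v = 25$,
  $\beta_0 = 0.3$ (about 1.4 stores per tract, ~130–170 stores citywide),
  structural-zero probability 0.15, populations log-uniform in
  [1,000, 8,000]. True effects follow the study narrative — fewer stores
  with segregation (entropy −0.5, Black clustering −0.5) and more with
  White clustering (+0.5), small positive percent-Asian/Hispanic effects
  (+0.02 per point), and *zero* SES effects, making the segregation-only
  model the generative truth for model selection. Magnitudes are the
  package's own choice: moderate effects sized to be detectable at
  n ≈ 100 so that single-realisation analyses carry signal.

The generator writes every latent truth (`u`, `v`, the structural-zero
mask, all parameters) to a truth file, which is the contract for
parameter-recovery tests.

**What the generator does not emulate.** Real tract fabrics are irregular
(variable degree, holes, rivers), populations and store counts are
spatially correlated with each other, covariates are measured with ACS
sampling error, and edge effects matter (the real workflow includes
stores just outside the boundary; the pipeline accepts such pre-augmented
tables rather than implementing buffer logic). Passing tests on the
lattice therefore demonstrate the *statistical machinery* — not that any
substantive conclusion transfers to a particular city.

# Validation results and their honest limits

The package's simulation studies (run in the test suite at reduced
replicate counts and chain lengths; sizes are stated in each test)
measure:

* *Parameter recovery* (50 replicates of the default design, model 4):
  coverage of the 95% credible intervals per coefficient, and the mean
  absolute log-scale bias of the posterior-mean estimates across the
  coefficient vector (the aggregate is reported because a single
  coefficient's 50-replicate bias estimate has Monte-Carlo error
  comparable to the quantity itself).
* A caveat found while validating: at this design's information content
  (~1.4 expected stores per tract), the *frequentist* coverage of
  equal-tailed 95% posterior intervals at the fixed true parameter point
  is about 0.89–0.95 depending on the coefficient. This is a property of
  the likelihood, not the sampler: maximum-likelihood Wald intervals on
  the same simulated designs show the same per-coefficient pattern to
  within Monte-Carlo error. Blanket "every coefficient covers ≥ 90% in
  every batch" expectations will therefore fail occasionally for the
  percentage-scale covariates even though the posterior is computed
  correctly.
* *Model selection*: with the segregation-only truth, the
  segregation-only model attains the minimum DIC in roughly 80% of
  replicates; most misses go to the full model, which nests the truth
  and wins whenever five null covariates soak up enough realisation
  noise to beat their ~1-point-per-parameter pD penalty. This, too, is
  intrinsic to conditional DIC at n ≈ 100 rather than a defect of the
  implementation; longer chains do not change the rate.
* *Exactness checks*: the ICAR energy, local G*, VIF and the ZIP
  likelihood against independent dense oracles (tolerance 1e-10); the
  precision Gibbs draw against its closed-form Gamma conditional
  (Kolmogorov–Smirnov); seeded byte-identical reproducibility of the
  whole pipeline.

# Numerical and design choices

* **Contiguity rule:** queen (any shared boundary point), the common
  census-tract practice. Polygon input is matched on shared vertices
  after rounding to 9 decimals — exact for lattices and conforming
  boundary layers; non-conforming polygon layers should be supplied as an
  explicit edge list. GeoJSON and edge-list inputs are supported.
* **Degenerate inputs:** constant surfaces in G* return all-zero z-scores
  with a warning; single-group cities make the entropy score undefined
  (error); zero-population tracts are dropped from H with a warning;
  perfectly collinear VIF columns report `Inf`; out-of-support sampler
  states have log-posterior $-\infty$.
* **Stability:** the ZIP zero-probability mixture is computed with
  log-space max-shifting so Poisson masses near underflow remain exact;
  proposals pushing the log-rate past 700 are rejected outright.
* **Scaled-down studies:** the test suite runs the simulation studies at
  2 chains × 4,000–6,000 iterations and the stated replicate counts;
  the acceptance study uses the full 4 × 20,000 reference protocol. A
  doubling-the-chain-length stability test guards the choice.

# Limitations

* Inference is re-implemented MCMC; agreement with deterministic
  approximate engines is expected at the level of posterior summaries,
  not draws.
* The intercept absorbs only the global mean of `u`, so disconnected
  graphs are handled approximately (with a warning); islands are given no
  structured effect at all.
* No WAIC/LOO, no hurdle or negative-binomial variants, no covariates on
  the zero process, no spatially varying coefficients.
* Shapefile input is not supported; convert to GeoJSON or an edge list.
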