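# zipbym

Bayesian spatial analysis of food-store counts over census tracts:
**z**ero-**i**nflated **P**oisson regression with **BYM**
(Besag–York–Mollié) spatial random effects, plus the segregation metrics,
model comparison and hotspot classification that surround it.

## The scientific problem

Whether a neighbourhood has a supermarket is shaped both by socioeconomic
conditions and by the long shadow of residential segregation. A standard
way to disentangle the two at census-tract resolution is to model the
tract-level count of supermarkets and grocery stores \(y_i\) as

\[
y_i \sim \pi_0\,\delta_0 + (1-\pi_0)\,\mathrm{Poisson}(\lambda_i),
\qquad
\log \lambda_i = \beta_0 + \textstyle\sum_k \beta_k x_{ik} + u_i + v_i + e_i,
\]

where \(u\) is an intrinsic CAR (Besag) spatially structured effect on
the tract contiguity graph, \(v\) iid Gaussian heterogeneity, \(e_i\) a
log-population exposure offset, and \(\pi_0\) a structural-zero
probability absorbing the excess of store-free tracts. Four nested models
are compared by DIC: (1) spatial effects only; (2) + racial-segregation
covariates — the tract entropy deviation score, Getis–Ord local-G*
high/low cluster classes for the Black and White populations, percent
Asian and percent Hispanic; (3) + socioeconomic covariates (poverty,
SNAP, no-vehicle, vacancy, college); (4) both blocks. Exceedance
probabilities \(\Pr(e^{u_i+v_i} > 1 \mid y)\) classify tracts as
hotspots (≥ 0.8), coldspots (< 0.2) or neither.

The package provides every stage as tested, reusable functions — graph
construction from GeoJSON/edge lists, segregation metrics, VIF screening,
an MCMC sampler written in C++, DIC comparison, hotspot classification,
and a one-call pipeline — together with a synthetic tract-lattice
generator so the whole workflow runs and validates without any external
data. See `vignettes/zipbym-methods.Rmd` for the full model, priors,
sampler and design discussion.

## Worked example

```r
library(zipbym)

study <- simulateStudy(seed = 42)   # 96-tract synthetic city
study$graph
#> AreaGraph with 96 areas, 326 edges, 1 component(s)
#>   degree: min 3 / mean 6.79 / max 8

fit <- fitMcmc(study$areaTable, study$graph, modelSpec(2), seed = 42)
summarizePosterior(fit)$coefficients
#>           term   rr ciLow ciHigh significant
#> 1    intercept 1.43  0.65   2.56       FALSE
#> 2 entropyScore 1.70  0.78   3.20       FALSE
#> 3 clusterBlack 0.44  0.23   0.76        TRUE
#> 4 clusterWhite 1.48  0.82   2.58       FALSE
#> 5     pctAsian 1.03  1.02   1.05        TRUE
#> 6  pctHispanic 1.01  1.00   1.02        TRUE

dic(fit, study$areaTable)[c("dic", "pD")]
#> $dic [1] 299.54      $pD [1] 6.94

table(exceedanceProbability(fit)$class)
#> coldspot  neither  hotspot
#>        0       96        0
```

Reading the output: each row is a rate ratio (RR), the multiplicative
change in expected store count per unit of the covariate, with its 95%
credible interval; a row is flagged significant when 1 lies outside the
interval. Here tracts classified as high Black clustering have
`percentChange(0.44)` = −56% fewer stores than low-clustering tracts
(this realisation was generated with a true effect of
exp(−0.5) ≈ 0.61), the DIC/pD pair feeds `compareModels()` across the
four model fits, and after the segregation covariates are accounted for
no tract's spatial effect exceeds the citywide level with probability
above 0.8 — the exceedance map is flat.

The full four-model pipeline, with every table written to disk plus a
run manifest, is one call:

```r
res <- runPipeline(study$areaTable, study$graph, "run1",
                   composition = study$composition, seed = 42)
res$comparison        # Table of DIC, pD, deltaDic, preferred, evidence
```

A thin command-line wrapper lives in `inst/scripts/zipbym-cli.R`
(`simulate` and `run` subcommands driven by a YAML config).

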