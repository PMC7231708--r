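# sdmspill

Spatial econometrics for balanced region-by-year panels: how does a
regressor of interest — the motivating case is government healthcare
expenditure — affect regional economic growth when regions influence their
neighbors? `sdmspill` implements the full workflow around the spatial
Durbin model (SDM)

    y_t = rho * W y_t + X_t beta + W X_t lambda + mu + eps_t

for a panel of `n` regions over `T` years: construction of the three
standard spatial weight matrices (border contiguity `W1`, inverse squared
great-circle distance `W2`, economic distance
`W3 = W2 %*% diag(ybar_i / ybar)`), yearly global Moran's *I* screening,
maximum-likelihood estimation with individual fixed or random effects,
Hausman model selection, and the LeSage–Pace partial-derivatives
decomposition of every coefficient into **direct**, **indirect**
(spillover) and **total** effects, with seeded Monte-Carlo inference.
A synthetic data generator simulates panels from the SDM reduced form at
the study design (31 regions x 13 years), so the entire pipeline is
testable without any external data.

Intended users: applied spatial econometricians and health-economics
researchers who need a scriptable, reproducible SDM stack in R.

## Worked example

```r
library(sdmspill)

cfg    <- synthetic_config(seed = 42)   # 31 units x 13 years, rho = 0.5
bundle <- synthetic_bundle(cfg)         # geography, weights, panel, partition

fe <- fit_sdm_fe(bundle$panel, sdm_spec(), bundle$weights)
fe
#> Spatial Durbin model (fixed effects), n = 31, T = 13
#>    term   estimate       se          z          p stars
#>    Heal  7.878e-02 0.005504  14.314957  1.765e-46   ***
#>     Cap  1.314e-01 0.005070  25.914774 4.539e-148   ***
#>     Con  5.500e-01 0.004791 114.800851  0.000e+00   ***
#>     Exp  1.185e-02 0.003865   3.065568  2.173e-03   ***
#>     Hum  3.754e-02 0.006659   5.637853  1.722e-08   ***
#>     Urb -3.212e-01 0.049251  -6.522398  6.919e-11   ***
#>  W.Heal -8.624e-05 0.010560  -0.008166  9.935e-01
#>   W.Cap  1.414e-02 0.011038   1.280988  2.002e-01
#>   W.Con -1.826e-01 0.025632  -7.122449  1.060e-12   ***
#>   W.Exp  6.460e-02 0.006801   9.498787  2.123e-21   ***
#>   W.Hum -1.604e-01 0.012007 -13.356070  1.092e-40   ***
#>   W.Urb -4.598e-01 0.088650  -5.186756  2.140e-07   ***
#>     rho  4.642e-01 0.041223  11.259506  2.079e-29   ***
#> sigma2 = 0.01843
#> log-likelihood = 218.966, pseudo-R2 = 0.9823
```

The estimator recovers the generator's truth (`rho = 0.5`,
`beta_Heal = 0.08`, ...) within sampling error. Spillovers are what the
coefficients cannot show directly; the decomposition turns them into
interpretable quantities:

```r
imp <- impact_inference(fe, bundle$weights, draws = 1000, seed = 43)
#>  regressor direct direct_sd indirect indirect_sd  total total_sd
#>       Heal  0.085     0.006    0.062       0.017  0.147    0.020
#>        Cap  0.144     0.006    0.128       0.017  0.272    0.020
#>        Con  0.562     0.005    0.124       0.017  0.686    0.020
#>        Exp  0.023     0.004    0.119       0.012  0.143    0.015
#>        Hum  0.014     0.008   -0.243       0.025 -0.229    0.030
#>        Urb -0.421     0.053   -1.037       0.158 -1.458    0.190
```

Reading the first row: a unit increase in log healthcare expenditure
raises own-region log GDP by 0.085 (direct effect), raises other regions'
log GDP by 0.062 in aggregate (indirect/spillover effect, transmitted
through the spatial multiplier `(I - rho W)^{-1}`), for a total effect of
0.147; the `*_sd` columns are Monte-Carlo dispersions from the estimated
sampling distribution. For a row-standardized `W` the total effect equals
`(beta_s + lambda_s) / (1 - rho)` exactly.

Yearly spatial-autocorrelation screening:

```r
moran_by_year(bundle$panel, bundle$weights)
#>  year      I expected variance      z     p
#>  2005  0.153   -0.033    0.017  1.418 0.078
#>  2006  0.086   -0.033    0.018  0.894 0.186
#>  2007 -0.197   -0.033    0.017 -1.267 0.897
#>  ...
```

The one-command pipeline (`run_analysis()`, or the `inst/cli/sdmspill`
script with `simulate | run | moran | fit | impacts | regions`
subcommands) writes the full report bundle — Moran tables, FE/RE
coefficient tables with Hausman and log-likelihood rows, impact tables,
regional refits under a region partition (the packaged China partition
splits 31 provinces 11/8/12 east/central/west), and a run log — as
deterministic delimited text: identical configuration and seed give
byte-identical outputs.

See `vignettes/spatial-durbin-spillovers.Rmd` for the model, the
estimation details, the synthetic data-generating process and the
package's numerical policies.

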