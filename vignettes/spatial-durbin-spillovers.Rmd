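---
title: "Spatial Durbin panel models and spillover decomposition with sdmspill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial Durbin panel models and spillover decomposition with sdmspill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmspill)
```

## The model

`sdmspill` analyzes a balanced panel of `n` regions observed over `T`
periods with the spatial Durbin model (SDM)

$$ y_t = \rho W y_t + X_t \beta + W X_t \lambda + \mu + \varepsilon_t, $$

where $W$ is an $n \times n$ spatial weight matrix, $\rho$ the spatial
autoregressive coefficient, $\lambda$ the coefficients on the spatial lags
of the regressors, and $\mu$ region effects that are either fixed
(conditioned on, absorbed by the within transformation) or random
(`N(0, sigma2_mu)`, independent of $X$). The motivating application is
regional economic growth (log GDP) regressed on government healthcare
expenditure and controls (fixed investment, retail consumption, exports,
human capital, urbanization share), all but the urbanization share on the
log scale. Because the SDM nests both the spatial lag and spatial error
models, it is the estimator of choice when the form of spatial dependence
is uncertain.

Assumptions worth keeping in view: strict exogeneity of the regressors,
homoskedastic disturbances, a correctly specified and *known* $W$, and — for
the random-effects variant — independence of $\mu$ from $X$.

## Spatial weights

Three constructions are provided, mirroring standard practice:

* `build_contiguity()` — binary first-order border contiguity (`W1`).
  Islands are allowed and keep an all-zero row (they receive no lag).
* `build_inverse_distance()` — $w_{ij} = 1 / D_{ij}^2$ (`W2`). The distance
  is the great-circle (haversine) distance between centroids with Earth
  radius 6371.0 km. The phrase "longitude and latitude distance" admits a
  literal planar reading; `distance = "euclidean_degrees"` provides it, but
  haversine is the defensible default for coordinates spanning a large
  country.
* `build_economic()` — `W3 = W2 %*% diag(ybar_i / ybar)`, scaling *columns*
  by relative mean per-capita output, exactly as the defining product is
  written. Written this way, the weight unit `i` places on `j` grows with
  `j`'s economic size. The alternative row-scaling reading is available via
  `side = "row"`. $\bar y_i$ is the time-mean over the full sample window.

`row_standardize()` is applied before any model fitting: it makes the lag a
neighborhood average, gives `rho` its usual interpretation, bounds the
admissible interval above by 1 (`rho_interval()`, computed from the real
parts of the cached spectrum), and yields the closed-form total-effect
identity used throughout the tests. Raw matrices remain available. For the
asymmetric `W3` the spectrum is complex; log-determinants sum
`Re(log(1 - rho * omega_k))`, whose imaginary parts cancel for real
matrices.

## Moran screening

`morans_i()` implements the global Moran statistic in its textbook
normalization (the cross-product of deviations over the biased variance
times the total weight). Inference defaults to the *randomization*
(permutation-moment) null — the yearly cross-sections are fixed samples, not
draws from a superpopulation — with the normality variance and a seeded
permutation null (`p = (1 + #{I* >= I}) / (1 + n_permutations)`) as
alternatives. The default alternative is one-sided upper-tail, since the
screening question is whether growth clusters in space; two-sided inference
is a flag away. `moran_by_year()` applies the statistic to every period.

## Estimation

Both panel estimators concentrate $\beta$, $\lambda$ and $\sigma^2$ out of
the likelihood analytically:

* **Fixed effects** (`fit_sdm_fe()`): within-demeaned data; the profile
  log-likelihood in `rho`,
  $L(\rho) = -\tfrac{nT}{2}\log(2\pi\hat\sigma^2(\rho)) + T\log|I - \rho W| - \tfrac{nT}{2}$,
  is maximized by bounded scalar search on
  `(rho_min + 1e-6, rho_max - 1e-6)` with tolerance `1e-8` — deterministic,
  no random starts. The Jacobian term uses the precomputed eigenvalues, so
  each evaluation costs two residual vectors.
* **Random effects** (`fit_sdm_re()`): quasi-demeaning with weight
  $\theta = \sqrt{\sigma^2_\varepsilon / (\sigma^2_\varepsilon + T\sigma^2_\mu)} \in (0, 1]$,
  jointly maximized over $(\rho, \theta)$ with L-BFGS-B; the likelihood
  carries the extra $\tfrac{n}{2}\log\theta^2$ Jacobian. $\theta = 1$
  collapses to the pooled spatial model (which the RE likelihood therefore
  dominates by nesting); $\theta \to 0$ approaches the within estimator. An
  intercept is included (it is not annihilated by quasi-demeaning).

Standard errors come from the analytic expected-information matrix at the
optimum for the fixed-effects fit (blocks in $\delta = (\beta, \lambda)$,
$\rho$, $\sigma^2$ built from $G = W(I - \rho W)^{-1}$), with a
central-difference Hessian (relative step `1e-5`) as fallback and as the
method for the random-effects fit. One deliberate choice: the information
matrix is evaluated at the degrees-of-freedom–consistent variance
`e'e / (nT - n - 2k)` rather than the ML `e'e / nT`. Within demeaning
removes `n` unit means; at `T = 13` the pure-ML choice shrinks every
standard error by about 4%, which is enough to push confidence-interval
coverage below nominal and to systematically distort the fixed-vs-random
variance comparison. The likelihood value and the point estimates remain
pure ML. The incidental-parameters (Lee–Yu) correction of `rho` itself is
*not* applied, matching the direct ML approach of the era this analysis
style comes from; at `T = 13` the remaining `rho` bias is an order of
magnitude below its standard error (the recovery experiment quantifies it).

Time effects (`time_effects = TRUE`, two-way within transformation) are
available but off by default: the selected specification in this analysis
style uses individual effects only. Regressors with no within variation are
dropped with a named warning rather than failing the fit. The reported
pseudo-R² is the squared Pearson correlation between observed and fitted
outcomes, with effects recovered from residual unit means.

## Hausman comparison

`hausman_test()` contrasts the shared $(\beta, \lambda)$ blocks
(`df = 2k`; `rho` and the RE intercept excluded):
$H = d'[V_{FE} - V_{RE}]^{-1} d$. Two numerical policies matter:

* *Validity.* The difference is declared valid when its spectrum is
  positive up to a relative tolerance (`1e-3` of the dominant eigenvalue);
  eigenvalues that are numerical zeros on that scale are dropped via a
  pseudo-inverse. An indefinite difference is reported as computed —
  possibly negative, flagged `valid = FALSE`, no p-value — never silently
  repaired. Negative Hausman entries in published tables are exactly this
  phenomenon surfacing in real data.
* *When the test is informative.* $V_{FE} - V_{RE}$ is estimated with noise
  of order $V/\sqrt{n}$, while its true magnitude is the FE/RE efficiency
  gap times $V$. The chi-squared approximation is therefore trustworthy
  only when the gap dominates: regressors with substantial between-unit
  variation and a modest unit-effect variance (θ near 1). At the study's
  own `n = 31` with strong unit effects the difference is nearly always
  numerically indefinite and the test degenerate — a structural feature of
  the design, not an implementation artifact. The package's size experiment
  accordingly runs on a wide cross-section (`n = 200`) with persistent
  regressors (`x_persistence = 0.9`) and `sigma_mu = 0.02`, where the
  statistic empirically follows its nominal chi-squared law.

The pipeline's model-selection rule prefers the fixed-effects fit when the
Hausman test rejects at 5% *or* is invalid, and the FE log-likelihood
exceeds the RE one; both criteria are logged.

## Impact decomposition

Because the reduced form is
$y = (I - \rho W)^{-1}(X\beta + WX\lambda + \dots)$, the derivative of
$y_i$ with respect to regressor $s$ in region $j$ is the $(i, j)$ entry of
$K_s(W) = M(W)(I\beta_s + W\lambda_s)$ with $M(W) = (I - \rho W)^{-1}$. The
package summarizes, as is standard: **direct** = mean diagonal of $K_s$,
**indirect** (spillover) = mean off-diagonal row sum, **total** = their sum.
Two exact identities anchor the tests: total = direct + indirect (by
construction), and for row-standardized $W$,
total$_s = (\beta_s + \lambda_s)/(1 - \rho)$ (geometric series on a
row-stochastic matrix). The multiplier is computed by dense solve, verified
against the truncated Neumann series.

Dispersion of the summaries is by Monte-Carlo simulation from
$N((\hat\beta, \hat\lambda, \hat\rho), \widehat{V})$ (1000 draws by
default, seeded, bitwise reproducible); draws with `rho` outside the
admissible interval are rejected — not truncated — with the rejection rate
logged and a warning past 50%. The published tables this layout mirrors do
not state their standard-error method; simulation from the estimated
sampling distribution is the package's choice.

## The synthetic data generator

No real yearbook panel ships with the package; `synthetic_config()` +
`simulate_sdm_panel()` generate balanced panels directly from the SDM
reduced form so every stage is testable end-to-end. Defaults are the study
conditions: `n = 31` units, `T = 13` periods labeled 2005–2017,
`rho = 0.5`, coefficient vectors echoing the published fixed-effects
estimates, and regressor locations/scales matching the published
descriptive statistics (e.g., log healthcare expenditure mean 4.901, log
GDP mean 9.241; scales set to range/4). Unit effects default to
`sigma_mu = 0.3` and disturbances to `sigma_eps = 0.15` on the log scale —
a persistent province effect of ±30% and idiosyncratic year-to-year noise
of ±15%, chosen once as realistic magnitudes for regional log-GDP data.
Geography is either a rook lattice or uniform random points joined by
Gabriel-graph edges (planar, contains the Euclidean minimum spanning tree,
hence connected).

What the generator does *not* emulate: cross-regressor correlation (real
growth covariates are strongly collinear; an `x_persistence` option adds
within-unit persistence, but columns stay mutually independent by default),
deflation or real-terms adjustment, measurement error, and China's actual
provincial map. Passing tests therefore demonstrate correctness of the
machinery under the stated DGP, not robustness to every feature of real
data. The urbanization share is drawn normal and clamped into (0, 1);
at the default mean 0.52 / sd 0.17 the clamp binds with probability below
0.5%.

Reproducibility contract: a single global seed with fixed per-stage
offsets (`derive_seed`), so identical configurations reproduce panels,
tables and Monte-Carlo summaries bitwise.

## Regional refits

`regional_analysis()` re-estimates the FE model inside each region of a
unit partition (the packaged China partition has the standard 11/8/12
east/central/west split; membership is data, editable). Weight matrices are
**rebuilt** from raw geography within each region — restricting borders and
recomputing distances, then re-standardizing — because slicing a
row-standardized matrix breaks its row sums. Regions with fewer than 4
units, or whose restricted contiguity graph leaves more than half the units
neighborless, are skipped with a warning.

## Numerical choices and degenerate inputs

* Unit ordering is frozen lexicographically at load time; every matrix and
  panel shares it, checked on entry.
* Balance violations, duplicates, missing values, nonpositive values under
  a log transform, and out-of-range urbanization shares are *errors* —
  the package never imputes. An urbanization column on the percent scale
  (all values above 1.5) is divided by 100; values in (1, 1.5] are
  rejected as ambiguous.
* `rho` optimization is bounded scalar search (tolerance `1e-8`); `theta`
  is box-constrained to `(1e-4, 1]`; estimates within `1e-6` of a bound
  raise a boundary flag.
* Variance matrices are symmetrized and spectrally checked; a
  non-positive-semidefinite `vcov` blocks impact inference with an error.
* Significance stars use the 1% / 5% / 10% thresholds throughout.

## Problem sizes used in the tests

The shipped experiments run at deliberately chosen sizes: recovery at the
study design (31 × 13, 200 replicates — `rho` bias below 0.01 and 95% CI
coverage between 0.92 and 0.98 in the packaged runs), Moran test size with
2000 null simulations, Hausman size with 300 valid replicates at
`n = 200`, and consistency sweeps over `T ∈ {4, 10, 24}` at `n = 16` with
40–60 replicates per point. These sizes make the full suite complete in a
few minutes on a single core while keeping Monte-Carlo error comfortably
inside each assertion's band.

## Known limitations

* No Lee–Yu bias correction and no dynamic (space–time) terms.
* GMM/2SLS estimators, standalone SLM/SEM, local Moran statistics and
  k-nearest-neighbor or kernel weights are out of scope.
* The Hausman comparison is reported honestly but is intrinsically fragile
  in small cross-sections with strong unit effects (see above).
* The random-effects fit assumes `mu` independent of `X`; with correlated
  effects (`correlated_fe` in the generator) it is inconsistent — that is
  precisely what the Hausman test is for.
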