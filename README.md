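# tgamweb

Threshold generalized additive models (TGAMs) and coupled Monte Carlo
simulation for annual food-web time series.

Pelagic food webs reorganise abruptly: the effect of grazing, climate or
fishing on a trophic level can change sign once a controlling variable —
phosphorus loading, planktivore abundance — crosses a tipping point.
`tgamweb` is for ecologists and biostatisticians who want to *detect* such
regime-dependent dynamics in short annual series, *quantify* the
thresholds, and then *couple* the fitted single-level models into one
food-web model that can be propagated forward and interrogated with
what-if scenarios.

## The model

Each trophic level `y` (phytoplankton PHY, zooplankton ZOO, gelatinous
plankton GEL, planktivorous fish FIS) is regressed on lag-1 covariates
through natural cubic regression splines (at most 4 knots per term), with
the regression structure switching at an estimated threshold:

    y_t = a           + Σ_j f_j^lo(x_{j,t-1}) + Σ_k f_k(w_{k,t-1}) + e_t   if z_{t-1} <= θ
    y_t = a + b       + Σ_j f_j^hi(x_{j,t-1}) + Σ_k f_k(w_{k,t-1}) + e_t   if z_{t-1} >  θ

θ is found by GCV grid search over order-statistic midpoints (or over an
(angle, intercept) grid when the threshold is a line in two variables, as
for the fish model in the (ZOO, GEL) plane).  Because a grid search
flatters GCV, threshold and additive models are compared by **genuine
leave-one-out cross-validation**, refitting the whole procedure —
threshold search included — for every left-out year.

The four fitted models are then coupled: predictions feed back as biotic
covariates while external drivers (PRE, F, SST, NAO, P) stay observed,
with noise added by resampling whole year-rows of residuals (preserving
their contemporaneous correlation across trophic levels).  A scenario
engine shifts a driver by a percentage of its mean under paired seeds and
diagnoses trophic-control changes from the slopes of consumer–resource
phase-space trajectories.

A synthetic-data module (`gen_drivers()`, `gen_foodweb()`,
`true_params_default()`) generates food webs with known thresholds,
regime effects and error correlation, so every stage is verifiable
without access to monitoring data.

## Worked example

```r
library(tgamweb)

drv <- gen_drivers(driver_params(n_years = 36), seed = 4)
dat <- gen_foodweb(true_params_default(), drv, seed = 4)

fw <- fit_foodweb(dat)
fw
#> Coupled food-web fit (4 models )
#>   PHY: theta(P) = 51.811, R2(adj) = 0.952, GCV = 0.06906
#>   ZOO: theta(FIS) = 0.138, R2(adj) = 0.932, GCV = 0.1025
#>   GEL: theta(FIS) = 0.138, R2(adj) = 0.922, GCV = 0.07973
#>   FIS: line in (ZOO, GEL): intercept -0.21 slope 1.73, R2(adj) = 0.917, GCV = 0.1067
```

With only 36 years the estimated thresholds sit close to the generating
truth (P threshold 52, FIS threshold 0.10, fish line slope 1): the
phosphorus threshold is recovered at 51.8 and the fish regimes are split
by a line of slope 1.73.  Per-model summaries give the Table-style layout
of regime, covariate, effective degrees of freedom and p-value:

```r
summary(fw$fits$GEL)
#> Response: GEL
#> Threshold (theta) 0.138 on FIS
#> Intercept: -0.8289
#>   regime covariate   edf   p_value
#> 1    low       ZOO 1.000 8.081e-08
#> 2   high       ZOO 1.096 4.009e-07
#> 3   high       PHY 1.367 5.629e-06
#> 4  whole       SST 1.981 2.742e-03
#> GCV = 0.079734  R2(adj) = 0.922  n = 35
```

Note the zooplankton effect present in both regimes — negative below the
fish threshold, positive above it — the kind of sign switch an additive
model cannot represent.  Genuine CV confirms the regime-switching model:

```r
cmp <- compare_models(model_structure("GEL", whole = c("ZOO", "PHY", "SST")),
                      published_structures()$GEL, gel_frame)
#> Genuine leave-one-out CV comparison
#>   additive (GAM):  0.632312
#>   threshold (TGAM): 0.145489
#>   selected: TGAM
```

Simulation and scenarios:

```r
sim <- simulate_foodweb(fw, n_runs = 1000, seed = 4)   # mean + 95% bands
plot(sim, data = dat)

scenario_grid(fw, targets = "P", deltas = c(-15, 15), window = 5:20,
              n_runs = 200, seed = 4)
#>   target delta    pair slope_baseline slope_scenario difference sign_flip
#> 1      P   -15 ZOO/PHY          0.348        -0.0166    -0.3648      TRUE
#> 2      P   -15 FIS/ZOO          0.156         0.2051     0.0488     FALSE
#> 3      P    15 ZOO/PHY          0.348         0.2756    -0.0726     FALSE
#> 4      P    15 FIS/ZOO          0.156         0.1390    -0.0173     FALSE
```

Each row compares the straight-line slope of a consumer–resource
phase-space trajectory between the baseline and a scenario run under the
same error draws: here the −15% phosphorus scenario flips the
zooplankton–phytoplankton trajectory while the fish–zooplankton link is
unaffected.  `run_pipeline(pipeline_config(...))` chains dataset →
fit → simulate → scenarios and writes CSVs, a JSON manifest and a log.

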