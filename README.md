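# aerowarn

An air-quality early-warning toolkit for hourly pollutant concentration
series (PM2.5, PM10, O3, CO, NO2, SO2), aimed at environmental-health
analysts who need both *forecasts* of pollutant levels and a *graded
assessment* of what those forecasts mean for air quality.

The package implements two coupled modules:

**Forecasting.** A hybrid one-step-ahead forecaster,
CEEMD–BBODE–LSSVM:

* *CEEMD* — complementary ensemble empirical mode decomposition splits a
  series into intrinsic mode functions using paired ± white-noise
  ensembles; removing the first (noise-like) mode denoises the series
  exactly (the modes and residue sum back to the input).
* *LSSVM* — least-squares support vector regression with Gaussian kernel
  `K(x_i, x_j) = exp(−‖x_j − x_i‖² / 2σ²)`; the dual problem is one
  bordered linear system, so fitted values are exactly linear in the
  targets, `ŷ = L y`.
* *BBODE* — a biogeography-based optimizer hybridised with differential
  evolution tunes `(σ, γ)` by validation MSE; the same optimizer drives
  the benchmark harness and the distribution fitting.
* *Intervals* — nonsymmetric prediction bands from the linear-smoother
  representation: bias by double smoothing `L ŷ − ŷ`, variance by
  smoothing squared residuals with a degrees-of-freedom correction,
  band `(ŷ − bias) ± z_{a/2} √variance`; scored by coverage probability
  `CP = mean(1{y_i ∈ [L_i, U_i]})` and average width
  `AW = mean(U_i − L_i)`.

**Evaluation.** A normal/half cloud-model multi-criteria grader: each
quality level's concentration interval `(B_min, B_max]` becomes a cloud
`Ex = (B_max+B_min)/2`, `En = (B_max−B_min)/3`, `He = 0.1·En`; an
observation's certainty under a cloud is
`μ = exp(−(x − Ex)² / 2En′²)` with `En′ ~ N(En, He²)` (half clouds
saturate at 1 on the closed side of the extreme levels); entropy-AHP
weights combine expert and data-driven weights
`W_i ∝ z_i ω_i`; the level certainty `U = Σ W_i μ_i` is averaged over
2000 Monte-Carlo repetitions and the level with maximal mean certainty
is assigned. Marginal distributions (Weibull, Gamma, Lognormal,
Log-logistic, Inverse Gaussian) are fitted by maximising CDF goodness
of fit R², and forecasts are compared with the Diebold–Mariano test.

## Worked example

Forecast a synthetic PM2.5-like series and grade the shipped reference
samples:

```r
library(aerowarn)

x <- generate_series(n_hours = 500, baseline = 45, seed = 1)
fc <- forecast_pipeline(x, ensemble_size = 20, tune_pop = 10,
                        tune_iter = 20, significance = c(0.1, 0.4),
                        seed = 2)
glance(fc)
#> # A tibble: 1 × 5
#>     mae  mape  rmse    r2     n
#>   <dbl> <dbl> <dbl> <dbl> <int>
#> 1  3.92  10.3  6.04 0.846    99
```

The tuned model explains ~85% of the held-out hourly variance with a
mean absolute error of ~3.9 µg/m³ (MAPE 10.3%); `lower_0.1`/`upper_0.1`
columns in `fc$forecast` carry the 90% prediction band, and
`autoplot(fc)` draws actuals, predictions and the band.

```r
ev <- evaluate_air_quality(load_fixture("eval_samples"), reps = 2000,
                           seed = 3)
ev[, c("case", "I", "II", "final_level")]
#> # A tibble: 9 × 4
#>   case      I      II final_level
#>   <chr> <dbl>   <dbl> <chr>
#> 1 A_1   0.460 0.292   I
#> 2 A_2   0.132 0.542   II
#> 3 A_3   0.912 0.114   I
#> 4 A_4   0.160 0.613   II
#> 5 A_5   0.128 0.0314  IV
#> 6 A_6   0.127 0.00856 III
#> 7 A_7   0.852 0.153   I
#> 8 A_8   0.814 0.165   I
#> 9 A_9   0.128 0.360   II
```

Sample A_3's mean certainty of belonging to level I (excellent air) is
0.912 — the concentrations sit at or below the level-I cloud centres for
five of six pollutants. A_2, A_4 and A_9 all grade level II but with
different certainties (0.542, 0.613, 0.360), which is the point of the
cloud model: the certainty degree ranks severity *within* a level.

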