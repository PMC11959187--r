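# fieldctmax

Analysis tools for field-based critical thermal maximum (CTmax) studies of
stream fishes — built for the common design in which wild fish at many
stream sites undergo streamside CTmax trials (a slow warming ramp to loss
of equilibrium) and each site's thermal history comes from a patchwork of
temperature loggers that must be completed from weather-station air
temperature before any thermal metric can be computed.

The package is aimed at thermal ecophysiologists and fisheries scientists
who need to go from raw logger/weather CSVs and per-fish trial records to
defensible estimates of thermal plasticity and risk.

## What it computes

**Stream-temperature imputation.** Hourly stream temperature is modelled
from lagged air temperature with two competing transfer models,

- linear: `T_stream = m · T_air(lag) + b`
- logistic: `T_stream = L / (1 + exp(−k (T_air(lag) − x0)))`

where `L` is the curve maximum, `k` the logistic growth rate and `x0` the
inflection point. The lag is chosen on an hourly grid by linear-model R²;
the logistic is fitted by Levenberg–Marquardt least squares; the winning
family is the one whose predictions correlate best with observations.
Predictions fill gaps in the recorded series but never overwrite recorded
hours, and every value carries a `recorded`/`imputed` flag.

**Acclimation-window selection.** CTmax is modelled with random-intercept
linear mixed models, `CTmax_ij = β0 + β1·acc_i + u_i + e_ij` with
`u_i ~ N(0, σ_u²)`, one ML fit per candidate window mean (1, 4, 8, 14, 30,
40 days before the trial) plus a null model, ranked by AIC with Akaike
weights and marginal/conditional R². The mixed-model likelihood is
profiled analytically down to a one-dimensional search over the variance
ratio `σ_u²/σ_e²` and is oracle- and `lme4`-checked in the test suite.

**Body size.** An additive model `CTmax ~ acc + s(fork length) + (site)`
with a penalized spline (via `mgcv`) quantifies the typically small,
hump-shaped body-size effect and locates its interior peak.

**Safety margins.** Per site: `TSM = mean CTmax − seasonal maximum stream
temperature` (1 May–31 Oct), sublethal variants (`threshold − max`, with
20 and 22.5 °C defaults), strict exceedance hours, and the acclimation
response ratio (ARR = the fitted acclimation slope, °C per °C).

**Synthetic studies.** A seeded generator produces air series (annual +
diel sinusoids + AR(1) weather), stream series (true lagged transfer +
noise), site-structured fish CTmax, and 4 °C/h trial ramps, so the whole
pipeline is testable offline. Defaults mirror a 20-site Ontario-style
brook trout study; see the methods vignette.

## Worked example

```r
library(fieldctmax)

study <- simulate_study(seed = 1)                      # 20 sites, 19 fish/site
acc   <- acclimation_table(study$stream, study$trial_times)
rk    <- select_window(study$fish, acc)
rk
#> <window_ranking> acclimation-window model selection (ML)
#>             model window_days K     AIC   dAIC weight cum_weight r2_conditional r2_marginal slope slope_se
#> 1 30-day + (Site)          30 4 411.940  0.000  0.525      0.525          0.773       0.595 0.175    0.022
#> 2 40-day + (Site)          40 4 412.159  0.219  0.471      0.996          0.773       0.592 0.167    0.021
#> 3 14-day + (Site)          14 4 422.010 10.070  0.003      1.000          0.773       0.470 0.161    0.030
#> ...
#> 7            Null          NA 3 438.166 26.226  0.000      1.000          0.773       0.000    NA       NA
#> best window: 30 days

attr(rk, "fits")[["30d"]]
#> <ctmax_lmm> ML fit: 370 fish, 20 sites
#>             Estimate Std.Error
#> (Intercept)  26.7837    0.3439
#> acc_30d       0.1751    0.0222
#>   sigma_u^2 = 0.1186, sigma_e^2 = 0.1504
#>   logLik = -201.970, AIC = 411.94, R2m = 0.595, R2c = 0.773

arr(attr(rk, "fits")[["30d"]])
#> <arr_result> ARR = 0.175 degC/degC (SE 0.022), basis: individual-level slope

tsm_table(study$fish, study$stream, study$season,
          trial_times = study$trial_times)[1:3, c("site_id", "mean_ctmax",
                                                  "season_max", "tsm")]
#>   site_id mean_ctmax season_max   tsm
#> 1  site01      28.38      11.89 16.49
#> 2  site02      28.19      13.03 15.16
#> 3  site03      28.83      14.04 14.79
```

Reading: the 30-day window gives the lowest AIC, with the 40-day window
statistically indistinguishable (ΔAIC 0.22) and short windows clearly
worse — the canonical pattern when windows overlap heavily. In this
realization CTmax rises 0.175 ± 0.022 °C per °C of 30-day acclimation (the
generator's true slope is 0.23; single-study estimates scatter around it
with the site-level design), site differences beyond acclimation remain
(R²c 0.773 vs R²m 0.595), and plasticity is partial (ARR « 1). Cold
groundwater-buffered sites carry double-digit safety margins.

For file-based workflows, `write_fixture_study()` emits a complete
CSV + YAML study and `run_pipeline()` (or the CLI wrapper in `inst/cli/`)
executes impute → metrics → model → TSM with all stage outputs on disk.

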