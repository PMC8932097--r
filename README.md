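# fiesclim

Quantifies how much of the recent rise in food insecurity can be
attributed to warming. The package is aimed at researchers working with
experience-scale food-security surveys and monthly climate series: it
builds region-year panels of food-insecurity prevalence from individual
eight-item survey responses, derives the climate covariates (annual
temperature anomalies against a 1981-2010 baseline, monthly anomaly
bins, SPI-6 drought counts), fits two-way fixed-effects panel
regressions in which the anomaly effect is allowed to differ by year,
and compares predicted prevalence under observed warming against a
counterfactual in which each region's temperature follows its
historical trend. A synthetic-data generator with known ground truth
replaces the restricted survey microdata and reanalysis inputs, so
every stage is testable end to end.

## The model

For region *i* and year *t*, prevalence (percent) of moderate-to-severe
or severe food insecurity is modelled as

```
y_it = alpha_i + tau_t + lambda_t * V_it
       + gamma_1 * SHDI_it / 0.1 + gamma_2 * D_it + e_it
```

with `V_it` the annual temperature anomaly (°C, vs the region's
1981-2010 mean), `SHDI` sub-national HDI in units of 0.1, and `D_it`
the number of months with six-month SPI below −1.5. The year-specific
slopes `lambda_t` — the quantity of interest — are estimated by OLS
with anomaly-by-year interactions and cluster-robust (by region)
inference; sequential one-sided Wald tests ask whether the path rises
year on year, and a path-equality test asks whether the two severity
outcomes respond differently. Attribution then evaluates the fitted
linear model under factual versus counterfactual anomalies and
averages within region groups.

## Worked example

```r
library(fiesclim)

climate <- simulate_climate(climate_gen_params(seed = 1))   # 83 regions, 1981-2019
panel   <- simulate_panel(climate, panel_gen_params(seed = 2))
fit     <- fit_tvc(panel, "sfi")
fit$lambda
#>   year estimate     se ci_low ci_high        p
#> 1 2014     1.29 0.0533   1.18    1.40 4.06e-39
#> 2 2015     1.45 0.0514   1.35    1.56 4.42e-44
#> 3 2016     1.53 0.0541   1.43    1.64 4.04e-44
#> 4 2017     1.54 0.0483   1.44    1.63 6.63e-48
#> 5 2018     1.57 0.0472   1.48    1.66 2.37e-49
#> 6 2019     1.54 0.0468   1.45    1.64 4.98e-49
```

Each row is the estimated effect of a 1 °C anomaly on severe
food-insecurity prevalence in that year, in percentage points (the
generator's truth rises from 1.40 to 1.64). Whether the path rises
significantly year on year:

```r
wald_sequential_test(fit)
#>   year_from year_to    diff    se statistic      p
#> 1      2014    2015  0.1639 0.052     3.137 0.0012
#> 2      2015    2016  0.0787 0.039     2.024 0.0231
#> 3      2016    2017  0.0031 0.049     0.062 0.4752
#> 4      2017    2018  0.0348 0.047     0.736 0.2320
#> 5      2018    2019 -0.0284 0.032    -0.899 0.8144
```

Counterfactual attribution (factual minus trend-extrapolated
counterfactual, percentage points; positive = warming left food
insecurity higher):

```r
scen   <- counterfactual_anomaly(climate)
groups <- attr(climate, "regions")[, c("region_id", "group")]
att    <- attribute(fit_tvc(panel, "msfi"), fit, panel, scen, groups)
att[, c("group", "msfi_difference", "sfi_difference")]
#>      group msfi_difference sfi_difference
#> 1   Africa           0.375          0.308
#> 2 Americas           0.348          0.286
#> 3     Asia           0.355          0.292
#> 4   Europe           0.363          0.297
```

The synthetic counterfactual removes only the ~0.2 °C of post-2010
excess warming built into the generator, hence differences of a few
tenths of a point; published attribution based on
no-anthropogenic-forcing climate models removes a much larger gap.

The numbered scripts under `analysis/` run the same pipeline as a
narrated workflow — simulate, indicators, score, fit, attribute —
writing tables under `results/`. The methods vignette
(`vignettes/climate-attribution-methods.Rmd`) documents the model,
the generator's calibration, inference choices and limitations.

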