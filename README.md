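# opioidits

Interrupted time series (ITS) analysis of monthly opioid-related death
rates in the U.S., with a no-COVID-19 counterfactual, excess-death
accounting, and Poisson parametric bootstrap confidence intervals.

## What problem this solves, and for whom

Epidemiologists and health-policy analysts studying the opioid epidemic
need to quantify how discrete events — the rise of heroin (2010), the
dominance of illicit fentanyl (2013), the opioid public health emergency
declaration (October 2017), the COVID-19 national emergency (March 2020),
and the CDC community health worker funding announcement (March 2021) —
changed the trajectory of opioid-related mortality, and how many deaths the
pandemic added over what would otherwise have occurred. `opioidits`
implements that full pipeline: ingestion of tab-separated mortality exports
(with final/provisional merging and small-cell suppression), ICD-10
record-level filtering, population interpolation and rate computation,
segmented regression with immediate and sustained intervention effects,
counterfactual projection, excess-death accumulation, and bootstrap
uncertainty — plus a synthetic-data generator so the whole pipeline is
testable without interactive access to the mortality database.

## The model

With $t$ the month index (January 1999 = 1), $I_t(E) = \mathbf{1}\{t \ge
\tau_E\}$ and $P_t(E) = \max(0, t - (\tau_E - 1))$ for each event $E$ at
month $\tau_E$, the monthly death rate per 100,000 persons is modelled as

$$
y_t = \beta_0 + \beta_1 t
 + \beta_2 I_t(\text{Heroin}) + \beta_3 P_t(\text{Heroin})
 + \beta_4 I_t(\text{Fentanyl}) + \beta_5 P_t(\text{Fentanyl})
 + \beta_6 P_t(\text{PHE})
 + \beta_7 I_t(\text{COVID}) + \beta_8 P_t(\text{COVID})
 + \beta_9 P_t(\text{CHW}) + \varepsilon_t,
$$

fitted by OLS per Census Region (or with a full gender interaction). The
no-pandemic counterfactual $\tilde y_t$ sets the COVID and CHW terms to
zero; the excess rate is $r_t = y_t - \tilde y_t$, absolute excess deaths
are $s_t = r_t p_t / 10^5$ with $p_t$ the day-interpolated population, and
cumulative excess is $c_t = \sum_{i \ge 255} s_i$ (March 2020 onward).
Confidence intervals come from resampling $d^*_t \sim \text{Poisson}(d_t)$
at every timepoint, refitting, and reprojecting, B times; national
intervals sum replicate curves across regions before taking quantiles. See
`vignettes/opioid-its-methods.Rmd` for assumptions, defaults, and
limitations.

## Worked example

Simulate the four regions from the bundled published coefficient estimates
(Poisson count noise, realistic regional populations), fit the South, and
bootstrap its cumulative excess:

```r
library(opioidits)

model  <- default_true_model()
pop    <- default_population_table()
series <- simulate_monthly_counts(model, pop, months = 1:286, seed = 42)

south <- subset(series, region == "South")
fit <- fit_its(build_design_matrix(south$t), south$rate)
fit
#> ITS regression fit: 286 observations, 10 terms
#> Residual SE 0.02572 on 276 df; R-squared 0.9975 (adj. 0.9974)
#> # A tibble: 10 × 5
#>    term                  estimate std.error statistic   p.value
#>    <chr>                    <dbl>     <dbl>     <dbl>     <dbl>
#>  1 Intercept             0.195    0.00450     43.3    4.67e-125
#>  2 Month                 0.00310  0.0000588   52.7    4.19e-146
#>  3 Indicator_Heroin     -0.000877 0.00982     -0.0893 9.29e-  1
#>  4 MonthsSince_Heroin   -0.00336  0.000417    -8.06   2.36e- 14
#>  5 Indicator_Fentanyl   -0.0666   0.0107      -6.23   1.76e-  9
#>  6 MonthsSince_Fentanyl  0.0108   0.000451    23.9    4.38e- 69
#>  7 MonthsSince_PHE      -0.00812  0.000522   -15.6    1.25e- 39
#>  8 Indicator_COVID       0.515    0.0169      30.4    3.96e- 90
#>  9 MonthsSince_COVID     0.0196   0.00169     11.6    1.89e- 25
#> 10 MonthsSince_CHW      -0.0181   0.00223     -8.12   1.61e- 14

bootstrap_cumulative_excess(south, B = 1000, seed = 43)
#> Poisson bootstrap: B = 1000, months 255..286
#> final-month cumulative excess 29675 (95.0% CI 28096 to 31166)
```

Reading the output: the fitted immediate COVID effect (0.515 deaths per
100,000, the level shift at March 2020) and the sustained effects recover
the generating truth (0.5231, etc.) within their standard errors — the
fentanyl slope change of +0.0108/month and the PHE slope change of
−0.0081/month are the dominant pre-pandemic forces. The bootstrap says the
pandemic added roughly 29,700 opioid-related deaths in this synthetic South
through October 2022, with a 95% interval of about 28,100–31,200.

File-based workflows go through `simulate_scenario()` (writes the
final/provisional export pair, population CSV, and truth YAML) and
`run_pipeline()` (parse → merge → rates → fit → counterfactual → excess →
bootstrap → national aggregate, writing coefficient tables, diagnostics,
excess series, CI tables, figures, and a run manifest).

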