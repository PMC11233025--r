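---
title: "Interrupted time series modelling of opioid-related mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrupted time series modelling of opioid-related mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opioidits)
```

## The scientific problem

The U.S. opioid epidemic has unfolded over decades in distinguishable waves
— prescription opioids, heroin, and illicit fentanyl — punctuated by policy
responses and, from March 2020, by the COVID-19 pandemic. `opioidits`
models monthly opioid-related death rates per 100,000 persons, stratified by
Census Region (Northeast, Midwest, South, West) and optionally by gender, as
a multi-intervention interrupted time series (ITS): a piecewise-linear
regression whose pieces are delimited by a small set of dated events. The
package then asks the counterfactual question — what would mortality have
looked like without the pandemic? — and converts the gap between observation
and counterfactual into excess and cumulative excess deaths with bootstrap
uncertainty.

## The model

Let $y_t$ be the opioid-related death rate (deaths per 100,000 per month) at
month index $t$, with $t = 1$ at January 1999. For each event $E$ with month
index $\tau_E$, define the step indicator $I_t(E) = \mathbf{1}\{t \ge
\tau_E\}$ and the elapsed time $P_t(E) = \max(0,\, t - (\tau_E - 1))$, so
$P = 1$ in the event month itself. The foundational model is

$$
y_t = \beta_0 + \beta_1 t
    + \beta_2 I_t(\mathrm{Heroin}) + \beta_3 P_t(\mathrm{Heroin})
    + \beta_4 I_t(\mathrm{Fentanyl}) + \beta_5 P_t(\mathrm{Fentanyl})
    + \beta_6 P_t(\mathrm{PHE})
    + \beta_7 I_t(\mathrm{COVID}) + \beta_8 P_t(\mathrm{COVID})
    + \beta_9 P_t(\mathrm{CHW}) + \varepsilon_t .
$$

Indicator coefficients are *immediate* effects (an instantaneous level
shift, deaths per 100,000); elapsed-time coefficients are *sustained*
effects (a change in slope relative to the pre-event trend, deaths per
100,000 per month). The default timeline and the month indices it implies:

```{r}
default_timeline()
```

The opioid public health emergency (PHE) declaration and the community
health worker (CHW) funding announcement fall late in their months, so they
enter with sustained effects only; their indicators exist (and are exposed
by `build_intervention_variables()` for inspection) but are not regression
columns. The design therefore has ten columns, and over January 1999 to
October 2022 (286 months) the fit has 276 residual degrees of freedom.

Gender enters through a fully interacted design
(`build_interaction_design()`): female rates are the baseline block and male
rates deviate through a second block of the same ten columns multiplied by a
male indicator. Because the interaction is complete, the stacked fit's point
estimates coincide exactly with separate per-gender fits — an identity the
test suite checks to machine tolerance.

## From counts to rates

Mortality tables report monthly death counts $d_{t,g}$ per stratum, while
population estimates are annual. Each monthly observation is anchored to the
final calendar day of its month. Annual population estimates are assigned to
July 1 and interpolated linearly in *elapsed days* between anchors
(`interpolate_population()`), with backfill before the first anchor and
carry-forward after the last. Day-based interpolation is the default because
it is the natural meaning of linear interpolation on a calendar; a
`"month-uniform"` switch exists for sensitivity checks, and the two differ
by well under 1% on realistic growth. The rate is then
$y_{t,g} = 10^5 \, d_{t,g} / p_{t,g}$, kept unrounded.

Record-level inputs are reduced to counts by an ICD-10 rule
(`opioid_code_rule()`): the underlying cause must be a drug-poisoning code
(X40–X44, X60–X64, X85, Y10–Y14) and at least one contributing cause must be
an opioid T code (T40.0–T40.4, T40.6). Matching is by exact normalized code
with ranges expanded to explicit lists, so T40.5 (cocaine) can never match by
prefix, and multiple qualifying T codes count a death once. Suppressed small
cells parse to missing values with a flag; any computation that would need a
suppressed cell fails loudly rather than imputing, with an explicit
`missing_as_zero` opt-in for gender aggregation.

## Counterfactual, excess, and attribution

The no-pandemic counterfactual
$\tilde y_t = \beta_0 + \beta_1 t + \cdots + \beta_6 P_t(\mathrm{PHE})$
is the fitted linear predictor with the COVID-19 level and slope terms and
the CHW slope term set to zero. `counterfactual_design()` zeroes those
columns and `counterfactual_predict()` refuses rows in which they are
nonzero, so pandemic terms cannot leak into the projection by accident. For
pre-pandemic months the counterfactual equals the full-model fit exactly.

For months from the pandemic onset ($t \ge 255$), the excess rate is
$r_t = y_t - \tilde y_t$, absolute excess deaths are
$s_t = r_t\, p_t / 10^5$, and cumulative excess is $c_t = \sum_{i=255}^t
s_i$. All excess quantities are kept real-valued internally and rounded only
for reporting. The excess-rate interval is the counterfactual prediction
interval reflected about the observed rate, treating the observed value as
fixed — the simplest construction consistent with reporting a prediction
band around the projection. National quantities are exact elementwise sums
over the four regions.

Attribution contextualizes the model against published all-cause excess
mortality: with non-COVID excess deaths nCED (given directly, or derived as
all-cause excess minus COVID-19 deaths), the opioid share is
$100 \cdot \mathrm{oCED} / \mathrm{nCED}$, reported to one decimal. When a
published table supplies both an nCED count and a COVID share, the printed
count is used in preference to re-deriving it, since published rows are not
always exactly reproducible from the share.

## Bootstrap uncertainty

Confidence intervals for cumulative excess deaths come from a five-step
Poisson parametric bootstrap (`bootstrap_cumulative_excess()`), run
separately per region: resample $d^*_t \sim \mathrm{Poisson}(d_t)$ at *all*
timepoints (including pre-pandemic months); recompute rates with the
original populations; refit the ITS regression; project the counterfactual
from the refitted coefficients; and accumulate excess deaths, where the
observed rates entering the excess are the resampled ones. Per-month bounds
are empirical quantiles (default 2.5% and 97.5%) over B replicates; B
defaults to 1000, which makes tail quantiles stable at desk scale. National
intervals sum replicate curves across regions replicate-by-replicate before
taking quantiles, preserving the within-replicate pairing; the national
point estimate is the sum of regional point estimates. Replicate refits use
the QR core of base R's least squares on the fixed design, so a
B = 1000 regional bootstrap takes well under a second. A failed replicate
fit is an error naming the replicate, never silently skipped.

Quantiles default to R's type 7 (inclusive linear interpolation) and the
estimator is configurable. Note one degenerate-case subtlety: at B = 2,
interpolating estimators do not return the replicate minimum and maximum;
the inverse-ECDF estimator (type 1) does.

## The synthetic-data generator

Because the real mortality database is only available interactively, the
generator (`true_model()`, `simulate_monthly_counts()`,
`simulate_certificates()`, `write_wonder_fixture()`) produces every input
the pipeline consumes from a known truth, making parameter recovery a
testable property. The truth is exactly the piecewise-linear model above:
this makes recovery well-posed, and a configurable AR(1) term on Gaussian
rate noise exists to probe violations of the independence assumption.

Defaults define the study conditions rather than a tuning surface:

* coefficients default to the bundled published regional estimates
  (`regional_its_coefficients()`), so the synthetic regime has realistic
  levels, slopes, and a realistic pandemic shock;
* populations default to round-number approximations of the four regions'
  resident populations (53.6M, 64.4M, 100.2M, 63.2M in 1999) with linear
  growth, anchored July 1;
* noise defaults to Poisson counts with mean $\mu_t p_t / 10^5$ — the same
  mechanism the bootstrap assumes.

Certificate simulation exercises the ICD filter: qualifying records carry a
random qualifying underlying code and at least one qualifying T code, while
a configurable contaminant admixture (fraction $f$ of all records, i.e.
$\mathrm{round}(n f / (1-f))$ added to $n$ genuine records) must fail the
filter by construction, via a non-poisoning underlying cause or the absence
of a qualifying T code. Fixture files render the series in the
tab-separated export dialect — header row, one row per stratum-month, the
literal token `Suppressed` below the small-cell cutoff (default 10), a
`---`-prefixed notes block — split into a final/provisional pair that
round-trips through the parser and merger.

What the generator does **not** emulate: reporting delays beyond the
final/provisional split, geographic or demographic microstructure below the
region-gender level, seasonality, and real-data curvature within segments
(the published analysis notes curvilinear stretches, e.g. the Midwest PHE
segment). Passing recovery tests therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not that the
piecewise-linear form is adequate for any particular real dataset.

## Numerical and inferential choices

* **Classical standard errors.** Inference uses homoskedastic OLS standard
  errors, matching default linear-model output. Under Poisson count noise
  the rate variance is proportional to the mean, which grows over the
  series; classical 95% CIs then undercover the late-segment (pandemic-era)
  coefficients while overcovering early ones. The suite verifies nominal
  coverage under Gaussian errors — the model's stated assumption — and
  unbiasedness (mean recovery) under Poisson noise; the heteroskedastic
  undercoverage is a known property of this estimator on count-derived
  rates, mirrored by the mild heteroskedasticity visible in real-data
  diagnostics.
* **No autocorrelation correction.** Monthly mortality series are serially
  dependent in practice; the package fits and reports plain OLS, and the
  generator's AR(1) switch lets users measure the consequence rather than
  hiding it.
* **Rank guard.** `fit_its()` rejects rank-deficient designs naming the
  collinear columns instead of silently dropping them; short segments
  (fewer than 8 observations on either side of an event) warn rather than
  error, since a late final segment is the common, analyzable case.
* **Determinism.** Every stochastic function takes a mandatory seed and
  scopes it with `withr::with_seed()`; nothing touches the global RNG
  state. Identical seeds give bitwise-identical series, replicates, and CSV
  outputs.
* **Problem sizes.** The test suite uses 286-month series, 400–500
  replicate fits for recovery and coverage checks, and bootstrap coverage
  over 200 outer replicates at B = 200; these sizes hold Monte-Carlo error
  near the tolerances being asserted while keeping the full suite under a
  minute.

## Limitations

The pipeline evaluates interventions fixed *a priori*; it does not detect
changepoints. It extrapolates only within the observed window, in keeping
with the retrospective purpose of ITS. Real-data headline quantities
(fitted coefficients, regional cumulative excess) depend on an interactive
data download and are bundled here only as published reference numbers; the
package's computed results on synthetic data should be compared against the
generating truth, which is what the test suite does.
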