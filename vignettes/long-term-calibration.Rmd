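---
title: "Methods: risk projection, long-term calibration, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk projection, long-term calibration, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammorisk)
```

This vignette is the package's own account of its models and the choices
behind them: what is assumed, which parameters matter, what the synthetic
cohort does and does not emulate, and where the design was genuinely open.

## 1. The risk engine

### Multiplicative relative hazard

The engine is deliberately a *multiplicative relative-risk surrogate*, not a
segregation/pedigree likelihood model. A woman's yearly hazard of invasive
breast cancer at age $a$ is

$$\lambda_i(a) = r_i \, d_i \, h_0(a),$$

with $r_i$ a product of per-factor relative risks over the classic
questionnaire factors and $d_i$ a normalized density multiplier. The
default factor relative risks are age-adjusted hazard-ratio estimates from a
large US screening registry cohort (e.g. one affected first-degree relative
1.71, two or more 2.04; atypical hyperplasia 4.50; BI-RADS extremely dense
2.21 against scattered as reference). Factors present in the data schema but
without published estimates — second-degree family history, ovarian-cancer
history, age of the youngest affected relative — default to 1.0 in every
category and exist purely as configuration points. Anything anchored to a
published number can be overridden from CSV (`read_rr_csv()`,
`read_density_csv()`, `read_rates_csv()`).

Two normalizations keep $h_0$ interpretable as the population rate:

* $r_i$ is divided by the prevalence-weighted mean factor product
  (`population_mean_rr()`), computed under independence of factors, with the
  pre-/post-menopausal BMI blocks blended by the configured status
  prevalence;
* $d_i = \mathrm{RR}(\text{birads}\mid\text{band}) \big/ \sum_c
  p(c\mid\text{band})\,\mathrm{RR}(c\mid\text{band})$ within age bands
  {<50, 50–59, ≥60} × BMI bands {<25, 25–30, ≥30, unknown}, so
  $E[d\mid\text{band}] = 1$ exactly. The default fills every band with the
  marginal estimates; the band structure is there so band-specific estimates
  can be dropped in when available.

Unknown answers are *kept*, not dropped, and contribute relative risk 1.0 —
a missing answer assigns the woman the population risk. Benign breast
disease enters through the most severe finding only (`benign_grade`); the
biopsy count is carried in the schema but not multiplied into the hazard,
because the biopsy-count and disease-grade estimates describe the same
biopsies and multiplying both would double-count them.

### Category-to-year dialect

Closed age intervals convert to their midpoint ("20-24" → 22). Open-ended
categories need a convention; the package fixes one documented dialect
(menarche "<11" → 10, "≥15" → 16; menopause "<30" → 27.5, "≥55" → 56;
first birth "≥40" → 41; affected-relative ages "<50" → 45, "≥50" → 60,
unknown → 50) and keeps it in one table so it can be replaced wholesale.
The exact published conversion rules for relatives' ages are not public;
this dialect is a stand-in and is flagged as such.

### Absolute risk with competing mortality

Ten-year risk uses an annual discrete cycle in which cancer precedes death
within a year:

$$q_k = 1 - e^{-r d\, h_0(a+k)}, \qquad
P(k{+}1) = P(k) + S(k)q_k, \qquad
S(k{+}1) = S(k)(1-q_k)e^{-m(a+k)}.$$

The cycle is exactly checkable against closed forms when $m \equiv 0$ and
against a monthly-step refinement when $m > 0$ (the tests bound the
discretization error at $10^{-3}$ absolute on a 10-year projection at
typical rates — the annual-vs-monthly difference is about $2\times10^{-4}$).
Competing mortality matters over long horizons: it removes women from risk
and keeps $P$ bounded well below the no-mortality value at older entry ages.

The bundled mortality column is a synthetic Gompertz female all-cause
hazard, $m(a) = 0.0013\,e^{0.085(a-40)}$, chosen so that death censors
roughly 2–3% of a screening cohort; it is a placeholder for a real life
table and is config-overridable. The bundled baseline $h_0$ interpolates
log-linearly between the two published anchor rates (1.3/1000/y at 42,
5.1/1000/y at 70) and is flat outside.

## 2. Expected events: why the net projection

Expected events use $E_i = -\ln(1-P_i)$ summed over women, with $P_i$ the
predicted cumulative incidence to the end of each woman's own follow-up.
This identity is martingale-exact only when $P_i$ is the *net* cumulative
incidence — the one ignoring competing mortality — because death already
terminates observed follow-up; including mortality in $P_i$ would
double-count it and bias $E$ downward. The pipeline therefore computes $E$
from the net cumulative hazard $r d \int h_0$ over the observed window
(`cum_hazard_net()`), while stratification uses the full
competing-mortality 10-year projection. With the hazard piecewise constant
on attained-age years, the integral is exact, which is what makes the
self-consistency tests sharp: a cohort simulated from the same hazards has
$E[O] = E$ exactly.

## 3. Validation statistics

* **O/E** with exact Poisson (Garwood) 95% bounds:
  $[\,q_\gamma(0.025; O)/E,\; q_\gamma(0.975; O+1)/E\,]$, lower bound 0
  when $O = 0$. The construction is verified in tests against direct
  inversion of the Poisson mass function and reproduces every published
  worked example to the printed precision.
* **Stratum table** over the clinical 10-year bands (left-closed,
  right-open; ≥8% is "high") with incidence rates per 1000 women-years and
  incidence-rate ratios against the average band (2–<3%) using the exact
  conditional-binomial rate-ratio interval — the published method for the
  IRR is unstated, so the standard exact construction was chosen.
* **Kaplan-Meier cumulative risk** per group via the product-limit
  estimator with Greenwood pointwise intervals; the test oracle is an
  independent brute-force enumeration over *all* event/censor patterns of
  size ≤ 6.
* **Decile hazard ratios**: indicators for the top and bottom deciles of
  predicted 10-year risk against the middle 80%, stratified by 5-year
  entry-age group. Decile boundaries are positional ranks with ties broken
  by id order — deterministic by construction. A top-5% variant covers the
  usual sensitivity analysis.
* **Calibration coefficient** $\beta$: follow-up expanded to woman-year
  records; covariate = log predicted yearly hazard; proportional-hazards
  fit stratified by 5-year entry-age group. On the log scale $\beta = 1$
  means relative risks are correctly scaled, which matches the way
  published coefficients below 1 are read as relative-risk
  overdispersion. Whether the original covariate entered on the natural or
  log scale is not decidable from the text; both are implemented
  (`scale = "natural"`), log is the default.
* **Calibration trend**: scaled Schoenfeld residuals, offset by
  $\hat\beta$, regressed linearly on follow-up year. The published spline
  is a visualization; `autoplot()` provides a LOESS smooth for plots, while
  the reported intercept/slope come from the linear fit. The lm-based
  intervals ignore residual autocorrelation at event times; they are
  symmetric and adequate for the null/recovery checks the package makes.
* **ΔLR-χ²**: twice the partial-log-likelihood difference between the
  age-only model (5-year entry-age factor) and the model adding the log
  predicted hazard, on identical expanded data — non-negative by nesting.
  Its null distribution is verified against $\chi^2_1$ by simulation.
* **Reclassification**: full 5×5 stratum cross-tabulation with per-cell
  events, person-years and incidence rates.

## 4. The synthetic cohort: what it emulates

`generate_cohort()` produces a screening cohort with:

* **Entry ages** from a two-peak mixture — 25% U[40,42), 20% U[50,52), 55%
  U[40,73) — reflecting risk-based screening start ages at 40 and 50 with
  median entry near 50. Only the peak locations and the overall range are
  anchored to observation; the weights are the package's own realistic
  choice and are configurable.
* **Factor prevalences** matching the published marginals (86/12.7/1.3% for
  affected first-degree relatives; 7.7/35.7/42.3/14.3% for density; and so
  on). Two dependencies are modelled, because the analysis assumes them:
  menopausal status follows entry age against a latent age at menopause
  ~N(48.5, 5.5²); density is assigned by rank of a latent Gaussian score
  loaded negatively on age and BMI (loadings −0.25, −0.35), with quota
  assignment by rank so the configured marginal is preserved *exactly*.
  All other factors are independent — the declared, testable assumption.
* **Outcomes** from the engine's own hazards with three miscalibration
  knobs: the true yearly hazard is
  $\gamma\,(r_i d_i)^{\kappa + \delta t}\, h_0(a)$. $\gamma$ scales
  absolute risk (detectable as O/E $\approx \gamma$), $\kappa$ rescales the
  log relative hazard (detectable as $\beta \approx \kappa$), and $\delta$
  drifts the coefficient per year (detectable as trend slope
  $\approx\delta$). The drift multiplies the *coefficient* rather than the
  baseline precisely so that it is identifiable by the trend statistic — a
  pure baseline drift $e^{\delta t}$ would be absorbed by the Cox baseline
  and no validation statistic could recover it.
* **Censoring** by the observed mix: competing death from the mortality
  table, constant DCIS and disenrollment hazards, age-75 cap, and an
  administrative cap at the end of an 18-year accrual window entered at a
  uniform offset. The disenrollment hazard is auto-tuned by bisection to
  hit the observed 47.2% disenrollment fraction, because the published
  quantity is the fraction, not the rate. Within each attained-age year all
  processes are constant-hazard and the earliest exponential wins.

**What it does not emulate.** Screening dynamics are absent: no sojourn
times, no screen-detection boost, no post-negative-screen rate deficit, no
secular trends. The observed age-dependence of calibration in real
screening cohorts (over-prediction in younger women, under-prediction in
older) arises from exactly those dynamics, so a green self-consistency test
establishes that the *statistics* are correct, not that the generator
reproduces registry behaviour. Race/ethnicity, income and geography are out
of scope throughout.

**A known small bias, on purpose.** The normalizer for $r$ assumes
independent factors, but the generator couples menopause to age and density
to age/BMI. The measured population mean of $r d$ is 0.992 rather than
1.000 at the defaults. The package documents this ~0.8% offset instead of
absorbing it into the normalizer: it is a faithful consequence of the two
declared couplings, it is well inside every tolerance used downstream, and
hiding it would make the normalization claim stronger than it is. The
self-consistency tests assert $|\,\overline{rd} - 1| < 0.02$.

## 5. Numerical and degenerate-input choices

* Hazards are piecewise constant on attained-age years (`h0(floor(a))`),
  shared exactly between engine, expected-events integral and simulator.
* Follow-up intervals are half-open $(entry, exit]$ with the event at exit;
  woman-year episodes shorter than $10^{-6}$ years are nudged to that
  length so the survival machinery never sees zero-length intervals.
* `oe_ratio(0, E)` returns a lower bound of exactly 0; empty strata emit
  rows with $O = 0$ and undefined IRR rather than erring.
* The risk-stratum cut is left-closed/right-open, so a predicted risk of
  exactly 2% is "average" and exactly 8% is "high".
* Seeds: `sim_config(seed =)` governs the whole generation; auto-tuning
  uses a derived sub-seed and then re-seeds, so tuned and fixed-hazard runs
  with the same seed produce the same records.

## 6. Known limitations

* The engine is not a pedigree model: BRCA carrier probabilities,
  second/third-degree likelihoods and hormone-therapy interactions are out
  of scope; the input schema is compatible, the internals are not.
* Band-specific density relative risks default to the marginals for lack of
  published conditional estimates; the structure is present but unexercised
  by defaults.
* The trend interval treats scaled Schoenfeld residuals as independent
  observations; for formal inference about time-varying effects at scale a
  dedicated method would be preferable.
* Confidence intervals on the calibration coefficient are Wald intervals
  from the partial likelihood; at a few hundred events they are wide
  (roughly ±0.15 at 650 events), so single-replicate point estimates
  scatter accordingly.
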