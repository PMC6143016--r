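# mammorisk

Long-term validation of absolute breast-cancer risk models that combine
classic questionnaire risk factors with BI-RADS mammographic density.

## The problem

Risk-adapted screening and preventive therapy need a risk model that stays
accurate for many years after a single assessment. Validating one against a
screening cohort requires a specific toolkit: each woman's predicted
cumulative incidence to the end of her own follow-up must be turned into an
expected event count, observed/expected ratios need exact Poisson intervals,
and relative-risk calibration has to be examined over follow-up time, not
just on average. `mammorisk` implements that toolkit together with the risk
engine it evaluates and a synthetic screening-cohort generator, so the whole
pipeline can be exercised and tested end to end without access to a
registry.

## The model

A woman's yearly hazard of invasive breast cancer is

```
lambda_i(a) = r_i * d_i * h0(a)
```

* `r_i` — product of per-factor relative risks over the classic factors
  (family history, age at first birth, menarche, menopause, benign breast
  disease, BMI by menopausal status, height), divided by the
  prevalence-weighted population mean so that the population-average
  relative hazard is 1. Unknown answers contribute 1.0 (the population
  risk).
* `d_i` — BI-RADS density multiplier, normalized within age/BMI bands:
  `d = RR(birads | band) / sum_c prevalence(c | band) * RR(c | band)`, so
  `E[d | band] = 1` and density reshapes risk without changing the
  population rate.
* `h0(a)` — baseline invasive-cancer hazard by age (default rises
  log-linearly from 1.3/1000/y at 42 to 5.1/1000/y at 70).

Ten-year absolute risk is accumulated by an annual cycle with competing
non-breast-cancer mortality:
`q_k = 1 - exp(-r d h0(a+k))`, `P(k+1) = P(k) + S(k) q_k`,
`S(k+1) = S(k)(1-q_k) exp(-m(a+k))`.

The validation statistics follow the standard external-validation playbook:
`E = sum_i -log(1 - P_i)` with exact (Garwood) Poisson 95% CIs for O/E;
stratum tables over the clinical 10-year-risk bands (<2%, 2–<3%, 3–<5%,
5–<8%, ≥8%); Kaplan-Meier cumulative-risk curves; top/bottom-decile hazard
ratios; a proportional-hazards calibration coefficient on the log yearly
predicted hazard (β = 1 means correctly scaled relative risks) with a
scaled-Schoenfeld linear trend over follow-up; and the likelihood-ratio
chi-square a model adds beyond age.

## Worked example

Simulate a 50,000-woman screening cohort from the engine's own hazards,
predict, and validate:

```r
library(mammorisk)

sim    <- generate_cohort(sim_config(n = 50000, seed = 42))
pred   <- predict_cohort(sim$cohort)
report <- run_validation(sim$cohort, pred)
print(report)
#> Overall O/E: 653 / 636.8 = 1.03 (95% CI 0.95-1.11)
#> Calibration coefficient (log scale): beta = 1.159 (95% CI 1.006-1.312)
#>   50000 women, 277535 woman-year records, 653 events
#>   trend slope: -0.0260/y (95% CI -0.0660 to 0.0141)
#>   LR chi-square beyond age: 214.6
```

653 cancers were observed against 636.8 expected — an O/E of 1.03 whose
exact Poisson interval comfortably covers 1, i.e. the model is calibrated
in the large on its own cohort. The calibration coefficient is near 1 —
its Wald interval sits marginally above 1 in this particular replicate,
which is sampling scatter at ~650 events (across replicate seeds the
coefficient averages 0.99) — and the trend slope interval covers 0: no
drift in relative-risk calibration over follow-up.

```r
dplyr::select(report$groups, stratum, n_women, observed, expected, ratio, ir)
#>   stratum   n_women observed expected ratio    ir
#> 1 all         50000      653    637.  1.03   2.59
#> 2 <2%         23493      154    169.  0.910  1.25
#> 3 2% to <3%   13123      179    172.  1.04   2.66
#> 4 3% to <5%    9647      194    181.  1.07   4.26
#> 5 5% to <8%    3131       98     86.3 1.14   7.27
#> 6 >=8%          606       28     28.9 0.968 10.9

decile_hr(sim$cohort, pred$p10)
#>   term      hr ci_low ci_high     n
#> 1 bottom 0.328  0.206   0.523  5000
#> 2 top    2.61   2.12    3.21   5000
```

Observed incidence climbs from 1.25 to 10.9 per 1000 women-years across the
predicted strata, and the top decile of predicted 10-year risk carries 2.6
times the hazard of the middle 80%.

Published worked examples reproduce directly from printed counts, e.g. the
high-risk stratum of the density model:

```r
oe_ratio(273, 349)
#>   observed expected ratio ci_low ci_high
#> 1      273      349 0.782  0.692   0.881
```

Tunable miscalibration knobs (`gamma` global scale, `kappa` power on the
relative hazard, `delta` per-year coefficient drift) let the test suite
verify that each statistic recovers a known truth.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline observed/expected calibration quantities — the O/E
point estimates for the high-risk stratum of both models and the lowest-risk
stratum, and the exact Poisson lower bound for the high-risk density-model
stratum — from their published observed and expected counts using the
installed package, and writes them as JSON.
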