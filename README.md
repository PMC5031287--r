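# riskstratsim

How good do candidate predictors have to be — how prevalent, and how
strongly associated with the outcome — before a clinical risk
prediction model built from them becomes clinically useful?

`riskstratsim` answers this by simulation, for researchers and
methodologists planning prediction studies. It generates a calibrated
synthetic obstetric cohort (preeclampsia among 75,225 overweight/obese
pregnant women: outcome incidence 8.4%, baseline logistic model AUC
0.68), injects hypothetical binary predictors with exact target
marginal prevalence *p* and univariable odds ratio *θ*, refits the
logistic model, and evaluates it across a factorial grid of
(*p*, *θ*, number of predictors *k*) — 120 configurations at the
defaults.

## The model and metrics

Outcomes are drawn from
`P(D=1|x) = logit⁻¹(β₀ + γ·xᵀβ)` with `β` the log crude odds ratios of
the published baseline predictors; `β₀` is solved so the mean risk
equals the target incidence and `γ` so the AUC of true risk against
outcome equals the discrimination target. Injected predictors are
Bernoulli(q₁) in cases and Bernoulli(q₀) in non-cases, with (q₀, q₁)
solved in closed form from (*p*, *θ*) and the realized incidence, so
the target crude OR holds exactly in expectation.

Each refit model is evaluated on:

- **Discrimination** — Mann–Whitney AUC (c statistic), with optional
  200-resample bootstrap optimism correction;
- **Risk stratification capacity** — the proportion of the population
  with predicted risk < 3% or > 15%, i.e. outside the band clinically
  equivalent to the 8.4% average (thresholds configurable);
- **Stratum likelihood ratios** — LR = (stratum cases/total cases) /
  (stratum non-cases/total non-cases) with log-method CIs; strata with
  LR > 10 or < 0.1 are *informative*;
- **Calibration** — observed-vs-expected tables and the
  Hosmer–Lemeshow test on deciles of risk;
- **Overall fit** — Nagelkerke's r².

## Worked example

```r
library(riskstratsim)

spec <- preeclampsia_cohort_spec()          # published marginals, n = 75,225
base <- cmd_calibrate(spec, seed = 20160921L)
base$report
#> Model performance report
#>   AUC 0.681 | Nagelkerke r2 0.076 | HL X2 7.55 (df 8, p 0.479)
#>   clinically distinct: 16.7% (low 1.3%, high 15.3%); informative LR: 0.0%
```

The calibrated baseline behaves like the published original model:
AUC ≈ 0.68, r² ≈ 0.07, adequate Hosmer–Lemeshow calibration, and no
stratum with an informative likelihood ratio — a model of little
clinical use. Now add five strong, common predictors (*θ* = 6,
*p* = 40%):

```r
ch  <- simulate_predictors(base$cohort, sim_predictor_spec(0.40, 6, 5L),
                           derive_seed(20160921L, 4L, 1L))
metrics_report(fit_logistic(ch))
#> Model performance report
#>   AUC 0.929 | Nagelkerke r2 0.517 | HL X2 9.55 (df 8, p 0.298)
#>   clinically distinct: 78.7% (low 63.6%, high 15.0%); informative LR: 63.6%
```

Discrimination jumps to 0.93 and 64% of the population lands in a
low-risk stratum whose likelihood ratio (0.08) would genuinely change
management — the kind of predictor battery needed before a prediction
model earns clinical use. The full grid runs with
`cmd_run(grid_config(), out_dir = "results")` and is summarized by
`cmd_report("results")`; a command-line wrapper with
`calibrate | run | report` subcommands ships in
`inst/scripts/riskstratsim.R`.

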