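# envgform

Parametric g-formula estimation of 27-year mortality risks under joint
hypothetical interventions on **blood lead**, **creatinine-corrected
urinary cadmium**, and **diet quality** — an adapted dietary inflammatory
index (DII) or daily fruit-and-vegetable (FV) servings.

## Who this is for

Environmental and nutritional epidemiologists asking "what would the
mortality distribution have looked like had everyone's metal exposures
been lowered and/or their diet improved?" in baseline-exposure cohort
data with survey weights. The package provides the full pipeline —
preprocessing, diet scoring, the estimator, bootstrap intervals,
reporting — plus a synthetic cohort generator with a *known* hazard model
and a brute-force counterfactual oracle, so the estimator is testable end
to end without restricted survey data.

## The method

For each cause of death (all-cause, cardiovascular, cancer), a
survey-weighted pooled logistic regression on person-year rows models the
discrete-time hazard

logit *h(t)* = β₀ + β₁t + β₂t² + β_L·log₂BLL + β_C·log₂UCd + β_D·D +
β_LD·log₂BLL·D + β_CD·log₂UCd·D + γ′Z

with D one diet exposure (DII or FV servings, separate fits), metals
mutually adjusted per doubling, and Z the adjustment set (age, sex,
ethnicity, income tertile, education, residence, smoking, BMI, physical
activity). An intervention rewrites the exposure columns (cap / floor /
set, targets as weighted percentiles of the observed distribution or
absolute values); the counterfactual 27-year risk is the weighted mean of
1 − ∏ₜ(1 − ĥ(t)) over participants. Contrasts are risk ratios and risk
differences versus the natural course and versus a worst-case scenario;
95% CIs come from a nonparametric bootstrap (M = 200, percentile method).

Measurement conventions: below-LOD lead imputed as LOD/√2 (0.7 µg/dL at
LOD 1.0), cadmium divided by urinary creatinine (µg/g), complete-case
exclusions with a logged reason per column. The DII is a signed weighted
sum of standardized, energy-adjusted component intakes over 24 components
(positive = anti-inflammatory in this adaptation); FV servings come from
coded food records via a serving-size registry.

## Worked example

```r
library(envgform)

cohort <- generate_cohort(cohort_config(n_participants = 4000, seed = 42))
prep   <- prepare_cohort(cohort)$cohort   # exclusions, LOD, log2 transforms

gs <- compute_geometric_stats(prep$blood_lead, prep$survey_weight)
sprintf("GM blood lead: %.2f ug/dL", gs$gm)
#> "GM blood lead: 2.96 ug/dL"

res <- run_gformula(prep, default_scenarios("dii"),
                    hazard_model_spec(diet = "dii"),
                    causes = "all", M = 50, seed = 1)
writeLines(render_results_table(res[res$reference == "natural_course", ]))
```

```
| Intervention      | Risk (%) | Risk ratio (95% CI) | Risk difference (95% CI) |
|---|---|---|---|
| natural_course    | 34.49 | 1                   | 0                        |
| lower_lead        | 31.31 | 0.91 (0.84 to 0.99) | -3.18% (-5.44 to -0.19)  |
| lower_cadmium     | 27.48 | 0.80 (0.73 to 0.87) | -7.02% (-9.22 to -4.55)  |
| lower_both_metals | 24.41 | 0.71 (0.59 to 0.79) | -10.08% (-13.86 to -7.24)|
| improve_diet      | 31.41 | 0.91 (0.88 to 0.93) | -3.08% (-4.27 to -2.24)  |
| best_case         | 25.63 | 0.74 (0.61 to 0.86) | -8.86% (-13.44 to -4.72) |
| worst_case        | 51.79 | 1.50 (1.39 to 1.63) | +17.30% (13.72 to 21.62) |
```

Reading it: under this synthetic cohort's (known, harmful-metal /
protective-diet) hazard model, capping both metals at their 5th
percentile lowers the estimated 27-year all-cause risk from 34.5% to
24.4% (RR 0.71); the joint best case and the worst case bracket the
natural course, as the generating model implies they must.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/envgform.R simulate --n 5000 --seed 1 --out cohort.csv
Rscript inst/cli/envgform.R run --cohort cohort.csv --diet dii --m 200 --out-dir results/
```

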