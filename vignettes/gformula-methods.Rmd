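---
title: "Methods: the parametric g-formula for joint metal and diet interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the parametric g-formula for joint metal and diet interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Blood lead (BLL, µg/dL) and urinary cadmium (UCd, µg per g creatinine) are
associated with all-cause, cardiovascular, and cancer mortality, plausibly
through inflammation and oxidative stress. If so, an anti-inflammatory diet
may partly offset their effects, and a *joint* intervention — lowering the
metals and improving the diet — may be more effective than either alone.
`envgform` implements the estimator used to ask that question in
observational cohort data: the parametric g-formula (g-computation) with
discrete-time pooled logistic hazard models, applied to hypothetical
interventions on exposure distributions.

Because the original analysis requires restricted-scale national survey
data linked to death-registry follow-up, the package pairs the estimator
with a synthetic cohort generator whose hazard model is fully known, plus
a brute-force counterfactual oracle. Every stage of the pipeline is
validated against that known truth.

## The estimator

### Discrete-time hazard model

Follow-up is arranged as person-time: one row per participant per year at
risk, up to `min(ceiling(followup), 27)`. For a cause of death $c$ the
hazard in year $t$ is modelled as

$$\operatorname{logit} h_i(t) = \beta_0 + \beta_1 t + \beta_2 t^2
 + \beta_L \log_2 \mathrm{BLL}_i + \beta_C \log_2 \mathrm{UCd}_i
 + \beta_D D_i
 + \beta_{LD} \log_2 \mathrm{BLL}_i \cdot D_i
 + \beta_{CD} \log_2 \mathrm{UCd}_i \cdot D_i
 + \gamma' Z_i$$

where $D_i$ is one diet exposure — the adapted dietary inflammatory index
(DII) or daily fruit-and-vegetable (FV) servings; the two diet analyses
are separate model fits — and $Z_i$ is the adjustment set (age, sex,
ethnicity, income-to-poverty tertile, education years, residence, smoking,
BMI, physical activity). Metals are mutually adjusted and enter per
doubling ($\log_2$), limiting the influence of their right-skewed tails.
The model is fitted by maximizing the survey-weighted Bernoulli
log-likelihood over person-time rows (weights as frequency-style weights);
deaths from competing causes are censored at their final interval
(cause-specific censoring).

### Counterfactual standardization

An intervention is an ordered list of rules acting on
`blood_lead`, `ucd_creat`, `dii` or `fv_servings`: *cap* ("lower to"),
*floor* ("increase to"), or *set*, with targets given as weighted
percentiles of the observed pre-intervention distribution or as absolute
values. All percentile targets are resolved before any rule modifies the
data. The shipped scenario set mirrors the headline analysis: lower each
metal to its 5th percentile, separately and jointly; improve the diet
(floor the DII at its 75th percentile — under this index's sign convention
a *higher* score is more anti-inflammatory — or floor FV servings at 5 per
day); a best case combining both; and a worst case (metals floored at
their 95th percentile, diet worsened). A 25th/75th metal parameterization
is available through the scenario YAML files or
`default_scenarios(metal_low = 25, metal_high = 75)`.

Because all covariates are measured at baseline, the counterfactual risk
has a closed form — no Monte-Carlo step is needed in the estimator. For
each participant the fitted model predicts $h_i(t)$ for $t = 1..27$ with
exposures set by the intervention and everything else fixed, and

$$\widehat{R} = \sum_i w_i \Big(1 - \prod_{t=1}^{27} (1 - \hat h_i(t))\Big)
  \Big/ \sum_i w_i .$$

Contrasts are risk ratios and risk differences (percentage points) versus
the natural course (no intervention) and versus the worst-case scenario.
The identity intervention reproduces the natural-course risk through the
same code path, so its RR is exactly 1 and RD exactly 0.

### Confidence intervals

Nonparametric bootstrap: participants are resampled with replacement
(whole-person resampling; weights travel with the person), percentile
targets are re-resolved, the model refitted, and all risks and contrasts
recomputed per replicate; the 2.5th and 97.5th percentiles over `M = 200`
replicates form the interval. Replicate streams are derived
deterministically from one root seed. Replicates whose refit fails are
dropped and logged; more than 10% failures is an error. Percentile
intervals are not forced to contain the point estimate; the bootstrap
resamples individuals, not survey design units (design-based variance is
out of scope).

## The synthetic cohort generator

The generator emulates the *statistical structure* of a US adult survey
cohort, not its sampling design or demographics:

- **Covariates**: age (mean 48, SD 18, truncated 20–90), sex, ethnicity,
  income tertile, education, residence, smoking, BMI, physical activity,
  with plausible US-adult frequencies.
- **Exposures**: log-normal BLL (geometric mean 2.97 µg/dL) and
  creatinine-corrected UCd (GM 0.36 µg/g), shifted by age, sex and smoking
  in the directions seen in descriptive tables of US survey data; urinary
  creatinine log-normal around 1.1 g/L. Lead is stored at its true value
  with a below-LOD flag (LOD 1.0 µg/dL; about 7% of draws); the
  preparation stage imputes LOD/√2.
- **Diet**: 24 component intakes log-normal conditional on energy, with
  anti-inflammatory components loading on a latent diet-quality factor;
  FV records as (food code, quantity) pairs from a small synthetic
  registry. The stored `dii` and `fv_servings` columns are produced by the
  package's own scoring functions, so generator and pipeline can never
  drift apart.
- **Mortality**: three cause-specific logistic hazards (CVD, cancer,
  other) sharing the exposure coefficients, simulated year by year; if
  several cause draws fire in one year the cause with the smallest uniform
  draw wins. Intercepts were calibrated once, by simulation, so the
  default cohort shows ≈36% 27-year all-cause mortality with ≈30% of
  deaths cardiovascular and ≈22% cancer. Survivors are administratively
  censored at 27 years (a `censor_range` option allows earlier uniform
  censoring; the default keeps the empirical 27-year risk directly
  observable, which the calibration checks use).
- **Weights**: log-normal with coefficient of variation 0.6, normalized
  to mean 1.

Default effect sizes (logit per doubling / per unit): lead 0.15, cadmium
0.20, DII −0.05, FV −0.04, metal×diet interactions −0.02/−0.01 — harmful
metals, protective diet, protection strengthening as the diet improves.

The **oracle** applies an intervention to the true exposures and either
simulates `n_reps` trajectories per participant from the true hazards
(`oracle_counterfactual_risk`, with a Monte-Carlo SE) or evaluates the
risk analytically (`exact_counterfactual_risk`), including the exact
tie-break probabilities for cause assignment.

## What validation can and cannot show

Three subtleties, found while validating, shape how the estimator is
checked; they are properties of the design, not bugs:

1. **Separate diet models.** The analysis fits DII and FV in separate
   models (as the study design prescribes). If the generating process
   gives *both* diet dimensions real effects, each single-diet model
   absorbs part of the omitted diet effect through their correlation.
2. **All-cause hazard shape.** The sum of three logistic cause hazards is
   not exactly logit-linear, so the all-cause pooled fit is only
   approximately well-specified (exact in the rare-event limit); the
   resulting bias in counterfactual shifts is of order one percentage
   point and does not vanish with n.
3. **Ties and the net risk.** Under the one-cause-per-death recording
   convention, the recorded cause-specific event probability is the crude
   sub-density, slightly below the cause hazard, so cause-specific fits
   under-estimate the net (competing-risk-eliminated) risk by a few
   tenths of a percentage point.

Consistency checks (oracle equivalence, parameter recovery, bootstrap
coverage) therefore run under `validation_true_model()`: a single active
cause (no ties; all-cause and cause-specific coincide), effects only for
the analysed diet exposure, and a negligible detection limit. Under that
model the pooled logistic is exactly well-specified, and at n = 50,000
the g-formula scenario risks agree with the oracle within two combined
standard errors across all scenarios. Qualitative checks — null-effect
behaviour, natural-course calibration, best < natural < worst ordering —
run under the richer default model. Passing these suites shows the
estimator is correct *when its model is correct* and well-behaved under
the realistic generator; it cannot show robustness to residual
confounding, exposure measurement error, or time-varying confounding
(covariates are baseline-only by design).

## Numerical and design choices

- **Weighted percentile**: inverse weighted ECDF with linear interpolation
  at cumulative-weight midpoints; continuous in p, equal-weight behaviour
  close to standard continuous sample quantiles. Percentile targets are
  always resolved on the pre-intervention weighted distribution.
- **Weighted SD** in DII standardization uses the population (denominator
  n) convention, making small worked examples exact.
- **Energy adjustment** uses the density method (per 1000 kcal),
  configurable per component; the residual-regression alternative can be
  represented by pre-adjusting intakes upstream.
- **DII sign**: the default convention scores positive = anti-inflammatory
  (this adaptation's convention); `"classic"` negates every score. The 24
  shipped component weights are synthetic placeholders with plausible
  signs — replace them with literature weights for real analyses. The
  alcohol *nutrient* (ethanol grams) is a component; alcoholic beverage
  items are not separately counted.
- **Below-LOD cadmium** uses the same LOD/√2 rule as lead when a flag
  column is present.
- **Time terms**: raw quadratic polynomial in the interval index by
  default (degree 1–3 configurable). IRLS convergence tolerance 1e-10
  (1e-8 within bootstrap replicates); rank deficiency and separation are
  errors, not warnings.
- **Coefficient uncertainty**: survey weights enter the estimating
  equations as frequency-style weights, but the reported coefficient
  covariance is the robust sandwich form (A⁻¹BA⁻¹ with the squared-weight
  score variance) — with heterogeneous weights the naive information
  understates the sampling variance by roughly 1 + CV(w)². The
  oracle-equivalence suite propagates this covariance through the
  standardization (delta method) to budget the estimator's sampling
  error; interval estimation for users still goes through the bootstrap.
- **Fit sizes used by the validation suites** (chosen once): oracle
  equivalence and parameter recovery at n = 50,000; identity/null suite
  at n = 5,000 with M = 50; coverage at 25 cohorts of n = 2,000 with
  M = 200 and a trimmed (age, sex, smoking) adjustment set, against the
  per-cohort true RR from the exact oracle.

## Known limitations

- Survey-design (Taylor linearization) variance and PSU/stratum bootstrap
  are not implemented; weights affect point estimates only.
- Cause-specific risks from `estimate_scenario_risk` are net risks
  (1 − ∏(1 − h_c)); crude cumulative incidences under competing risks are
  available from the oracle for synthetic data but not as an estimator.
- Covariates are baseline-only; the generator and estimator share that
  restriction, so time-varying confounding is neither generated nor
  adjusted for.
- The generator's food-code vocabulary and DII weights are synthetic; real
  analyses must supply real registries.
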