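Package: envgform
Title: Parametric G-Formula for Joint Interventions on Metal Exposures and Diet Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates 27-year all-cause and cause-specific mortality risks under
    hypothetical interventions on blood lead, creatinine-corrected urinary cadmium,
    and diet quality (an adapted dietary inflammatory index or daily fruit-and-
    vegetable servings) using the parametric g-formula with survey-weighted pooled
    logistic discrete-time hazard models, metal-by-diet interaction terms, and
    nonparametric bootstrap percentile confidence intervals. Includes a synthetic
    cohort generator with a fully known discrete-time hazard model and a brute-force
    Monte-Carlo counterfactual oracle, so every stage of the pipeline is testable
    without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
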