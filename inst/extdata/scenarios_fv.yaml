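# Default intervention scenarios, fruit-and-vegetable-servings analysis.
# Improving the diet raises everyone to at least 5 servings/day (the
# guideline minimum); the worst case caps servings at 2/day and raises
# both metals to their 95th percentile.
scenarios:
  - name: natural_course
    rules: []
  - name: lower_lead
    rules:
      - {variable: blood_lead, mode: cap, percentile: 5}
  - name: lower_cadmium
    rules:
      - {variable: ucd_creat, mode: cap, percentile: 5}
  - name: lower_both_metals
    rules:
      - {variable: blood_lead, mode: cap, percentile: 5}
      - {variable: ucd_creat, mode: cap, percentile: 5}
  - name: improve_diet
    rules:
      - {variable: fv_servings, mode: floor, value: 5}
  - name: best_case
    rules:
      - {variable: blood_lead, mode: cap, percentile: 5}
      - {variable: ucd_creat, mode: cap, percentile: 5}
      - {variable: fv_servings, mode: floor, value: 5}
  - name: worst_case
    rules:
      - {variable: blood_lead, mode: floor, percentile: 95}
      - {variable: ucd_creat, mode: floor, percentile: 95}
      - {variable: fv_servings, mode: cap, value: 2}
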