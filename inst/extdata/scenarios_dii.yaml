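# Default intervention scenarios, dietary-inflammatory-index analysis.
# Metal percentiles follow the headline tables (5th / 95th); the
# alternative parameterization uses 25th / 75th. Under the index's sign
# convention a HIGHER score is more anti-inflammatory, so improving the
# diet floors the score at its 75th percentile and worsening it caps the
# score at its 25th.
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
      - {variable: dii, mode: floor, percentile: 75}
  - name: best_case
    rules:
      - {variable: blood_lead, mode: cap, percentile: 5}
      - {variable: ucd_creat, mode: cap, percentile: 5}
      - {variable: dii, mode: floor, percentile: 75}
  - name: worst_case
    rules:
      - {variable: blood_lead, mode: floor, percentile: 95}
      - {variable: ucd_creat, mode: floor, percentile: 95}
      - {variable: dii, mode: cap, percentile: 25}
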