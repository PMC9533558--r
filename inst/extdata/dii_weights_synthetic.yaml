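# SYNTHETIC inflammatory weight registry for the adapted dietary
# inflammatory index. The 24 component names are the real index components;
# the weights are placeholders with plausible signs and magnitudes only
# (positive = anti-inflammatory contribution under the default sign
# convention). Replace `weight` values with literature weights for use on
# real data. `energy_adjust: true` expresses the component per 1000 kcal
# (density method) before standardization.
components:
  - {name: carbohydrate,        weight: -0.10, energy_adjust: true}
  - {name: protein,             weight:  0.02, energy_adjust: true}
  - {name: alcohol,             weight:  0.28, energy_adjust: true}
  - {name: fiber,               weight:  0.66, energy_adjust: true}
  - {name: cholesterol,         weight: -0.11, energy_adjust: true}
  - {name: saturated_fat,       weight: -0.37, energy_adjust: true}
  - {name: monounsaturated_fat, weight:  0.01, energy_adjust: true}
  - {name: omega3,              weight:  0.44, energy_adjust: true}
  - {name: omega6,              weight:  0.16, energy_adjust: true}
  - {name: niacin,              weight:  0.25, energy_adjust: true}
  - {name: thiamin,             weight:  0.10, energy_adjust: true}
  - {name: riboflavin,          weight:  0.07, energy_adjust: true}
  - {name: vitamin_b6,          weight:  0.37, energy_adjust: true}
  - {name: vitamin_b12,         weight: -0.11, energy_adjust: true}
  - {name: iron,                weight: -0.03, energy_adjust: true}
  - {name: magnesium,           weight:  0.48, energy_adjust: true}
  - {name: zinc,                weight:  0.31, energy_adjust: true}
  - {name: vitamin_a,           weight:  0.40, energy_adjust: true}
  - {name: vitamin_c,           weight:  0.42, energy_adjust: true}
  - {name: vitamin_d,           weight:  0.44, energy_adjust: true}
  - {name: vitamin_e,           weight:  0.42, energy_adjust: true}
  - {name: folic_acid,          weight:  0.19, energy_adjust: true}
  - {name: beta_carotene,       weight:  0.58, energy_adjust: true}
  - {name: caffeine,            weight:  0.11, energy_adjust: false}
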