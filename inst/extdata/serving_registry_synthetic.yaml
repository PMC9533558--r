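# SYNTHETIC fruit/vegetable serving registry. Codes are invented (they do
# not follow the USDA seven-digit scheme); serving sizes are in grams and
# loosely follow dietary-guideline serving estimates. `excluded` entries
# are fruit-containing sweets whose main ingredient is not a fruit; their
# records contribute zero servings.
foods:
  - {code: F001, group: fruit,     serving_size: 150}   # apple
  - {code: F002, group: fruit,     serving_size: 120}   # banana
  - {code: F003, group: fruit,     serving_size: 130}   # orange
  - {code: F004, group: fruit,     serving_size: 145}   # grapes
  - {code: F005, group: fruit,     serving_size: 150}   # melon
  - {code: F006, group: fruit,     serving_size: 125}   # berries
  - {code: V001, group: vegetable, serving_size:  90}   # broccoli
  - {code: V002, group: vegetable, serving_size:  80}   # carrots
  - {code: V003, group: vegetable, serving_size:  30}   # leafy greens, raw
  - {code: V004, group: vegetable, serving_size:  85}   # green beans
  - {code: V005, group: vegetable, serving_size: 120}   # potatoes
  - {code: V006, group: vegetable, serving_size:  85}   # tomatoes
  - {code: V007, group: vegetable, serving_size:  80}   # corn
  - {code: V008, group: vegetable, serving_size:  90}   # peppers
  - {code: X001, group: excluded}                       # fruit-filled pastry
  - {code: X002, group: excluded}                       # fruit candy
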