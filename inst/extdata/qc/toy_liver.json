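[
  {
    "name": "universal: biomass maintenance on rich medium",
    "medium": {
      "EX_glc[h]": [-1000, 1000], "EX_lac[h]": [-1000, 1000],
      "EX_ala[h]": [-1000, 1000], "EX_urea[h]": [-1000, 1000],
      "EX_o2[h]": [-1000, 1000], "EX_co2[h]": [-1000, 1000],
      "EX_h2o[h]": [-1000, 1000], "EX_h[h]": [-1000, 1000]
    },
    "target": {"BIOMASS[h]": 1},
    "expectation": "feasible_positive"
  },
  {
    "name": "hepatic: gluconeogenesis from lactate",
    "medium": {
      "EX_glc[h]": [0, 1000], "EX_lac[h]": [-10, 0],
      "EX_ala[h]": [0, 0], "EX_urea[h]": [0, 1000],
      "EX_o2[h]": [-1000, 0], "EX_co2[h]": [0, 1000],
      "EX_h2o[h]": [-1000, 1000], "EX_h[h]": [-1000, 1000]
    },
    "target": "glc[h_e]",
    "expectation": "feasible_positive"
  },
  {
    "name": "hepatic: gluconeogenesis from alanine",
    "medium": {
      "EX_glc[h]": [0, 1000], "EX_lac[h]": [0, 0],
      "EX_ala[h]": [-10, 0], "EX_urea[h]": [0, 1000],
      "EX_o2[h]": [-1000, 0], "EX_co2[h]": [-1000, 1000],
      "EX_h2o[h]": [-1000, 1000], "EX_h[h]": [-1000, 1000]
    },
    "target": "glc[h_e]",
    "expectation": "feasible_positive"
  },
  {
    "name": "hepatic: urea synthesis from alanine nitrogen",
    "medium": {
      "EX_glc[h]": [0, 1000], "EX_lac[h]": [0, 0],
      "EX_ala[h]": [-10, 0], "EX_urea[h]": [0, 1000],
      "EX_o2[h]": [-1000, 0], "EX_co2[h]": [-1000, 1000],
      "EX_h2o[h]": [-1000, 1000], "EX_h[h]": [-1000, 1000]
    },
    "target": "urea[h_e]",
    "expectation": "feasible_positive"
  },
  {
    "name": "hepatic: no glucose without a carbon source",
    "medium": {
      "EX_glc[h]": [0, 1000], "EX_lac[h]": [0, 0],
      "EX_ala[h]": [0, 0], "EX_urea[h]": [0, 1000],
      "EX_o2[h]": [-1000, 0], "EX_co2[h]": [0, 1000],
      "EX_h2o[h]": [-1000, 1000], "EX_h[h]": [-1000, 1000]
    },
    "target": "glc[h_e]",
    "expectation": "zero"
  }
]
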