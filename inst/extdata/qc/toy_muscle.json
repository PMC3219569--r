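[
  {
    "name": "universal: biomass maintenance on rich medium",
    "medium": {
      "EX_glc[m]": [-1000, 1000], "EX_lac[m]": [-1000, 1000],
      "EX_ala[m]": [-1000, 1000], "EX_nh4[m]": [-1000, 1000],
      "EX_h2o[m]": [-1000, 1000], "EX_h[m]": [-1000, 1000]
    },
    "target": {"BIOMASS[m]": 1},
    "expectation": "feasible_positive"
  },
  {
    "name": "myocyte: ATP production from glucose",
    "medium": {
      "EX_glc[m]": [-10, 0], "EX_lac[m]": [0, 1000],
      "EX_ala[m]": [0, 1000], "EX_nh4[m]": [0, 0],
      "EX_h2o[m]": [-1000, 1000], "EX_h[m]": [-1000, 1000]
    },
    "target": {"ATPM[m]": 1},
    "expectation": "feasible_positive"
  },
  {
    "name": "myocyte: alanine export from glucose and ammonium",
    "medium": {
      "EX_glc[m]": [-10, 0], "EX_lac[m]": [0, 1000],
      "EX_ala[m]": [0, 1000], "EX_nh4[m]": [-10, 0],
      "EX_h2o[m]": [-1000, 1000], "EX_h[m]": [-1000, 1000]
    },
    "target": "ala[m_e]",
    "expectation": "feasible_positive"
  },
  {
    "name": "myocyte: no ATP without a carbon source",
    "medium": {
      "EX_glc[m]": [0, 0], "EX_lac[m]": [0, 1000],
      "EX_ala[m]": [0, 1000], "EX_nh4[m]": [0, 0],
      "EX_h2o[m]": [-1000, 1000], "EX_h[m]": [-1000, 1000]
    },
    "target": {"ATPM[m]": 1},
    "expectation": "zero"
  }
]
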