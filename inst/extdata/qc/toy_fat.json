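[
  {
    "name": "universal: biomass maintenance on rich medium",
    "medium": {
      "EX_glc[a]": [
        -1000,
        1000
      ],
      "EX_fa[a]": [
        -1000,
        1000
      ],
      "EX_pyr[a]": [
        -1000,
        1000
      ],
      "EX_o2[a]": [
        -1000,
        1000
      ],
      "EX_co2[a]": [
        -1000,
        1000
      ],
      "EX_h2o[a]": [
        -1000,
        1000
      ],
      "EX_h[a]": [
        -1000,
        1000
      ],
      "EX_glyc[a]": [
        -1000,
        1000
      ]
    },
    "target": {
      "BIOMASS[a]": 1
    },
    "expectation": "feasible_positive"
  },
  {
    "name": "adipocyte: triacylglycerol storage from glucose and fatty acids",
    "medium": {
      "EX_glc[a]": [
        -10,
        0
      ],
      "EX_fa[a]": [
        -10,
        0
      ],
      "EX_pyr[a]": [
        0,
        1000
      ],
      "EX_o2[a]": [
        -1000,
        0
      ],
      "EX_co2[a]": [
        0,
        1000
      ],
      "EX_h2o[a]": [
        -1000,
        1000
      ],
      "EX_h[a]": [
        -1000,
        1000
      ],
      "EX_glyc[a]": [
        0,
        1000
      ]
    },
    "target": {
      "TAGSTOR[a]": 1
    },
    "expectation": "feasible_positive"
  },
  {
    "name": "adipocyte: pyruvate release from glucose",
    "medium": {
      "EX_glc[a]": [
        -10,
        0
      ],
      "EX_fa[a]": [
        0,
        0
      ],
      "EX_pyr[a]": [
        0,
        1000
      ],
      "EX_o2[a]": [
        -1000,
        0
      ],
      "EX_co2[a]": [
        0,
        1000
      ],
      "EX_h2o[a]": [
        -1000,
        1000
      ],
      "EX_h[a]": [
        -1000,
        1000
      ],
      "EX_glyc[a]": [
        0,
        1000
      ]
    },
    "target": "pyr[a_e]",
    "expectation": "feasible_positive"
  },
  {
    "name": "adipocyte: glycerol release from glucose",
    "medium": {
      "EX_glc[a]": [
        -10,
        0
      ],
      "EX_fa[a]": [
        0,
        0
      ],
      "EX_pyr[a]": [
        0,
        1000
      ],
      "EX_o2[a]": [
        -1000,
        0
      ],
      "EX_co2[a]": [
        0,
        1000
      ],
      "EX_h2o[a]": [
        -1000,
        1000
      ],
      "EX_h[a]": [
        -1000,
        1000
      ],
      "EX_glyc[a]": [
        0,
        1000
      ]
    },
    "target": "glyc[a_e]",
    "expectation": "feasible_positive"
  },
  {
    "name": "adipocyte: no triacylglycerol without fatty acids",
    "medium": {
      "EX_glc[a]": [
        -10,
        0
      ],
      "EX_fa[a]": [
        0,
        0
      ],
      "EX_pyr[a]": [
        0,
        1000
      ],
      "EX_o2[a]": [
        -1000,
        0
      ],
      "EX_co2[a]": [
        0,
        1000
      ],
      "EX_h2o[a]": [
        -1000,
        1000
      ],
      "EX_h[a]": [
        -1000,
        1000
      ],
      "EX_glyc[a]": [
        0,
        1000
      ]
    },
    "target": {
      "TAGSTOR[a]": 1
    },
    "expectation": "zero"
  }
]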