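{
  "name": "absorptive",
  "bound_overrides": {
    "EX_lac[bl]": [0, 1000],
    "EX_ala[bl]": [0, 1000],
    "EX_urea[bl]": [0, 1000],
    "EX_pyr[bl]": [0, 1000],
    "EX_glyc[bl]": [0, 1000],
    "EX_o2[bl]": [-1000, 1000],
    "EX_h2o[bl]": [-1000, 1000],
    "EX_co2[bl]": [-1000, 1000],
    "EX_hco3[bl]": [-1000, 1000],
    "EX_glc[bl]": [-10, 0],
    "EX_fa[bl]": [-3, 0],
    "EX_nh4[bl]": [-5, 0],
    "ATPM[a]": [1, 1000],
    "ATPM[m]": [2, 1000]
  },
  "objectives": [
    {
      "objective": {
        "TAGSTOR[a]": 1
      },
      "direction": "max",
      "fix_fraction": 1
    },
    {
      "objective": {
        "ALAt[m]": 1
      },
      "direction": "max",
      "fix_fraction": 0.5
    },
    {
      "objective": {
        "ATPM[m]": 1
      },
      "direction": "max",
      "fix_fraction": 1
    }
  ],
  "deactivate_tissues": [],
  "carbon_sources": ["EX_glc[bl]", "EX_fa[bl]"],
  "carbon_sinks": {
    "triacylglycerol": "TAGSTOR[a]"
  }
}
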