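{
  "name": "starvation",
  "bound_overrides": {
    "EX_glc[bl]": [0, 1000],
    "EX_lac[bl]": [0, 1000],
    "EX_urea[bl]": [0, 1000],
    "EX_nh4[bl]": [0, 1000],
    "EX_fa[bl]": [0, 1000],
    "EX_pyr[bl]": [0, 1000],
    "EX_glyc[bl]": [0, 1000],
    "EX_o2[bl]": [-1000, 1000],
    "EX_h2o[bl]": [-1000, 1000],
    "EX_co2[bl]": [-1000, 1000],
    "EX_hco3[bl]": [-1000, 1000],
    "EX_ala[bl]": [-6, 0],
    "ATPM[h]": [30, 1000],
    "ATPM[m]": [2, 1000]
  },
  "objectives": [
    {
      "objective": {
        "EX_glc[bl]": 1
      },
      "direction": "max",
      "fix_fraction": 1
    }
  ],
  "deactivate_tissues": [],
  "carbon_sources": "EX_ala[bl]",
  "carbon_sinks": {
    "glucose": "EX_glc[bl]",
    "urea": "EX_urea[bl]"
  }
}
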