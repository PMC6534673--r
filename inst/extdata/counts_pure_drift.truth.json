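{
  "scenario": "pure_drift",
  "p0": 0.13,
  "alpha": null,
  "alpha_hun": null,
  "alpha_ie": null,
  "final_pool_freq": {
    "indo_european": 0.1552,
    "sekler": 0.166,
    "ural_siberian": 0.1186
  }
}
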