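{
  "scenario": "independent_pulses",
  "p0": 0.4,
  "alpha": null,
  "alpha_hun": 0.3,
  "alpha_ie": 0,
  "final_pool_freq": {
    "indo_european": 0,
    "sekler": 0.1382,
    "ural_siberian": 0.5028
  }
}
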