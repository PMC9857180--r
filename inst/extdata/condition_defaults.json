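{
  "rates_per_min": {"ST": 0.00246, "ST+Fe": 0.00244, "ST+MF": 0.00260, "ST+MF+Fe": 0.00260},
  "N0_per_ml": 1e6,
  "times_min": {"from": 0, "to": 1000, "n": 11},
  "sigma": 0.05
}
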