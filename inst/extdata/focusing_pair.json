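{
  "label": "focusing_pair",
  "stripes": [
    {"a1_mm": 23, "a3_mm": 5, "x0_mm": -23, "z0_mm": 0, "Br_T": 1.2, "sense": -1, "axis": "z"},
    {"a1_mm": 23, "a3_mm": 5, "x0_mm": 23, "z0_mm": 0, "Br_T": 1.2, "sense": 1, "axis": "z"}
  ]
}
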