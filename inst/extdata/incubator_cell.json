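{
  "label": "incubator_cell",
  "stripes": [
    {"a1_mm": 23, "a3_mm": 5, "x0_mm": 0, "z0_mm": -23, "Br_T": 1.2, "sense": -1, "axis": "x"},
    {"a1_mm": 23, "a3_mm": 5, "x0_mm": 0, "z0_mm": 23, "Br_T": 1.2, "sense": 1, "axis": "x"}
  ]
}
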