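{
  "b0": -1.385,
  "b_dmean": 0.093,
  "b_volume": -0.188,
  "metadata": {
    "alpha_beta": 3,
    "endpoint": "hypothyroidism at 12 months after neck IMRT",
    "units": {
      "dmean": "Gy (EQD2)",
      "volume": "cc"
    }
  }
}
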