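{
  "components": [
    {"category": "A", "mu_x": 26.67, "mu_y": 50.00, "sigma_x": 10, "sigma_y": 10},
    {"category": "A", "mu_x": 50.00, "mu_y": 73.33, "sigma_x": 10, "sigma_y": 10},
    {"category": "B", "mu_x": 50.00, "mu_y": 26.67, "sigma_x": 10, "sigma_y": 10},
    {"category": "B", "mu_x": 73.33, "mu_y": 50.00, "sigma_x": 10, "sigma_y": 10}
  ],
  "prior_a": 0.5,
  "realization": {
    "pixel_base": 850,
    "pixel_growth": 1.0181,
    "freq_base": 220,
    "freq_octave_div": 120,
    "box_edge": 150
  }
}
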