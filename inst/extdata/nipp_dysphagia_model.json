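{
  "name": "NIPP dysphagia grade II-IV at 6 months (original)",
  "intercept": -4.05,
  "coefficients": {
    "dmean_oral_cavity": 0.03,
    "dmean_pcm_superior": 0.02,
    "dmean_pcm_medium": 0.01,
    "dmean_pcm_inferior": 0.01,
    "tumour_location": 1,
    "baseline_dysphagia": 1
  },
  "coding": {
    "tumour_location": {"pharynx": 1, "larynx": 0},
    "baseline_dysphagia": {"grade_2_or_higher": 1, "below_grade_2": 0}
  }
}
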