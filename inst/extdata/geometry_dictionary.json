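{
  "_comment": "Ideal covalent geometry by element composition (sorted element pairs / triplets with the vertex element in the middle). Values follow standard small-molecule/protein restraint libraries; sigmas are generic restraint widths. Editable; unknown types are skipped with a warning.",
  "bonds": {
    "C-C": {"ideal": 1.53, "sigma": 0.02},
    "C-N": {"ideal": 1.47, "sigma": 0.02},
    "C-O": {"ideal": 1.42, "sigma": 0.02},
    "C-S": {"ideal": 1.81, "sigma": 0.025},
    "O-P": {"ideal": 1.6, "sigma": 0.02},
    "N-N": {"ideal": 1.4, "sigma": 0.02},
    "N-O": {"ideal": 1.4, "sigma": 0.02}
  },
  "angles": {
    "C-C-C": {"ideal": 111.0, "sigma": 2.0},
    "C-C-N": {"ideal": 111.0, "sigma": 2.0},
    "C-C-O": {"ideal": 109.5, "sigma": 2.0},
    "C-O-C": {"ideal": 111.0, "sigma": 2.0},
    "C-N-C": {"ideal": 114.0, "sigma": 2.5},
    "C-O-P": {"ideal": 120.5, "sigma": 2.5},
    "O-C-O": {"ideal": 109.5, "sigma": 2.0},
    "O-P-O": {"ideal": 104.0, "sigma": 2.5}
  }
}
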