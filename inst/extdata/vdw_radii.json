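{
  "_comment": "Van der Waals radii (Angstrom) for heavy-atom clash analysis; standard published consensus values (Bondi-style), H included for completeness.",
  "radii": {
    "H": 1.2, "C": 1.7, "N": 1.55, "O": 1.52, "P": 1.8, "S": 1.8,
    "F": 1.47, "CL": 1.75, "BR": 1.85, "I": 1.98, "SE": 1.9,
    "MG": 1.73, "ZN": 1.39, "FE": 1.4, "NA": 2.27, "K": 2.75, "CA": 2.31
  }
}
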