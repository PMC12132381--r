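{
  "_comment": "Hydrogen-bond polarity taxonomy of side-chain (and nucleotide) heavy atoms. class: donor_only | mixed | acceptor_only | nonpolar. Backbone amide/carbonyl atoms are deliberately excluded for amino acids; side-chain atoms only. Nucleotide entries cover ribonucleotides (and 2'-deoxy via the same names minus O2').",
  "residues": {
    "LYS": {"class": "donor_only", "donor_atoms": ["NZ"], "acceptor_atoms": []},
    "ARG": {"class": "donor_only", "donor_atoms": ["NE", "NH1", "NH2"], "acceptor_atoms": []},
    "HIS": {"class": "mixed", "donor_atoms": ["ND1", "NE2"], "acceptor_atoms": ["ND1", "NE2"]},
    "SER": {"class": "mixed", "donor_atoms": ["OG"], "acceptor_atoms": ["OG"]},
    "THR": {"class": "mixed", "donor_atoms": ["OG1"], "acceptor_atoms": ["OG1"]},
    "TYR": {"class": "mixed", "donor_atoms": ["OH"], "acceptor_atoms": ["OH"]},
    "ASN": {"class": "mixed", "donor_atoms": ["ND2"], "acceptor_atoms": ["OD1"]},
    "GLN": {"class": "mixed", "donor_atoms": ["NE2"], "acceptor_atoms": ["OE1"]},
    "TRP": {"class": "donor_only", "donor_atoms": ["NE1"], "acceptor_atoms": []},
    "ASP": {"class": "acceptor_only", "donor_atoms": [], "acceptor_atoms": ["OD1", "OD2"]},
    "GLU": {"class": "acceptor_only", "donor_atoms": [], "acceptor_atoms": ["OE1", "OE2"]},
    "CYS": {"class": "mixed", "donor_atoms": ["SG"], "acceptor_atoms": ["SG"]},
    "MET": {"class": "nonpolar", "donor_atoms": [], "acceptor_atoms": []},
    "ALA": {"class": "nonpolar", "donor_atoms": [], "acceptor_atoms": []},
    "VAL": {"class": "nonpolar", "donor_atoms": [], "acceptor_atoms": []},
    "LEU": {"class": "nonpolar", "donor_atoms": [], "acceptor_atoms": []},
    "ILE": {"class": "nonpolar", "donor_atoms": [], "acceptor_atoms": []},
    "PRO": {"class": "nonpolar", "donor_atoms": [], "acceptor_atoms": []},
    "PHE": {"class": "nonpolar", "donor_atoms": [], "acceptor_atoms": []},
    "GLY": {"class": "nonpolar", "donor_atoms": [], "acceptor_atoms": []},
    "A": {"class": "mixed", "donor_atoms": ["N6", "O2'"], "acceptor_atoms": ["N1", "N3", "N7", "O2'", "O4'", "OP1", "OP2", "O5'", "O3'"]},
    "G": {"class": "mixed", "donor_atoms": ["N1", "N2", "O2'"], "acceptor_atoms": ["O6", "N3", "N7", "O2'", "O4'", "OP1", "OP2", "O5'", "O3'"]},
    "C": {"class": "mixed", "donor_atoms": ["N4", "O2'"], "acceptor_atoms": ["O2", "N3", "O2'", "O4'", "OP1", "OP2", "O5'", "O3'"]},
    "U": {"class": "mixed", "donor_atoms": ["N3", "O2'"], "acceptor_atoms": ["O2", "O4", "O2'", "O4'", "OP1", "OP2", "O5'", "O3'"]}
  }
}
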