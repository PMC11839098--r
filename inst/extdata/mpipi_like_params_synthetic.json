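{
  "comment": "SYNTHETIC residue-level force-field parameter set in the style of sticker-and-spacer coacervate models (one bead per nucleotide or amino acid). Charges follow the published convention (nucleotides -1 e, arginine +1 e, proline 0); masses are residue masses (amu); Wang-Frenkel sticker wells (eps, kJ/mol) are representative values constructed so that adenine-adenine pi-stacking is the strongest nucleotide-nucleotide well (A > G-like > C ~ U) and nucleotide-arginine cation-pi wells exceed nucleotide-proline contacts. These are NOT the published model's fitted values; replace this file to use a fitted parameter set.",
  "beads": [
    {"name": "A", "class": "nucleic", "mass": 329.2, "charge": -1, "sigma": 6.2},
    {"name": "U", "class": "nucleic", "mass": 306.2, "charge": -1, "sigma": 6.0},
    {"name": "C", "class": "nucleic", "mass": 305.2, "charge": -1, "sigma": 5.9},
    {"name": "G", "class": "nucleic", "mass": 345.2, "charge": -1, "sigma": 6.3},
    {"name": "R", "class": "amino", "mass": 156.2, "charge": 1, "sigma": 6.6},
    {"name": "P", "class": "amino", "mass": 97.1, "charge": 0, "sigma": 5.6}
  ],
  "wf_defaults": {"mu": 2, "nu": 1, "rc_over_sigma": 3},
  "pairs": [
    {"a": "A", "b": "A", "eps": 5.0},
    {"a": "U", "b": "U", "eps": 2.4},
    {"a": "C", "b": "C", "eps": 2.6},
    {"a": "G", "b": "G", "eps": 5.6},
    {"a": "A", "b": "U", "eps": 3.4},
    {"a": "A", "b": "C", "eps": 3.5},
    {"a": "A", "b": "G", "eps": 5.2},
    {"a": "U", "b": "C", "eps": 2.5},
    {"a": "U", "b": "G", "eps": 3.6},
    {"a": "C", "b": "G", "eps": 3.8},
    {"a": "A", "b": "R", "eps": 4.2},
    {"a": "U", "b": "R", "eps": 3.0},
    {"a": "C", "b": "R", "eps": 3.1},
    {"a": "G", "b": "R", "eps": 4.5},
    {"a": "A", "b": "P", "eps": 1.0},
    {"a": "U", "b": "P", "eps": 0.8},
    {"a": "C", "b": "P", "eps": 0.8},
    {"a": "G", "b": "P", "eps": 1.1},
    {"a": "R", "b": "R", "eps": 0.8},
    {"a": "R", "b": "P", "eps": 0.5},
    {"a": "P", "b": "P", "eps": 0.5}
  ]
}
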