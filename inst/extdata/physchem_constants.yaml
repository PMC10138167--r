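# Physicochemical constants used by the annotation module.
#   residue_mass : average (isotope-weighted) residue masses in Da,
#                  ExPASy/ProtParam convention; a peptide adds one water.
#   kyte_doolittle : hydropathy scale (Kyte & Doolittle 1982).
#   pka : Bjellqvist pKa set as used by ProtParam-style pI calculators;
#         nterm/cterm carry residue-specific overrides plus a default.
water_mass: 18.01524
residue_mass:
  "A": 71.0788
  "R": 156.1875
  "N": 114.1038
  "D": 115.0886
  "C": 103.1388
  "E": 129.1155
  "Q": 128.1307
  "G": 57.0519
  "H": 137.1411
  "I": 113.1594
  "L": 113.1594
  "K": 128.1741
  "M": 131.1926
  "F": 147.1766
  "P": 97.1167
  "S": 87.0782
  "T": 101.1051
  "W": 186.2132
  "Y": 163.1760
  "V": 99.1326
kyte_doolittle:
  "I": 4.5
  "V": 4.2
  "L": 3.8
  "F": 2.8
  "C": 2.5
  "M": 1.9
  "A": 1.8
  "G": -0.4
  "T": -0.7
  "S": -0.8
  "W": -0.9
  "Y": -1.3
  "P": -1.6
  "H": -3.2
  "E": -3.5
  "Q": -3.5
  "D": -3.5
  "N": -3.5
  "K": -3.9
  "R": -4.5
pka:
  side_chain:
    "D": 4.05
    "E": 4.45
    "H": 5.98
    "C": 9.0
    "Y": 10.0
    "K": 10.0
    "R": 12.0
  nterm:
    default: 7.5
    "A": 7.59
    "M": 7.0
    "S": 6.93
    "P": 8.36
    "T": 6.82
    "V": 7.44
    "E": 7.7
  cterm:
    default: 3.55
    "D": 4.55
    "E": 4.75
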