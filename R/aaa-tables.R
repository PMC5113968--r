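# Residue code tables shared across the package.

# 3-letter -> 1-letter code for the 20 standard amino acids
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# Common chemically modified residues and the parent one-letter code.
# Anything not listed renders as 'X'.
MODIFIED_PARENT <- c(
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C"
)

WATER_CODES <- c("HOH", "WAT", "DOD")
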