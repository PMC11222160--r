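REMARK synthetic fixture: lipid headgroup pseudo-atoms plus one quinone-like ligand atom
ATOM      1  P   POP L   1       1.500   2.500   3.500  1.00  0.00           P
ATOM      2  P   POP L   2      -4.250   0.000   3.500  1.00  0.00           P
ATOM      3  P   POP L   3       6.000  -3.250   3.500  1.00  0.00           P
ATOM      4  C1  POP L   2      -4.250   0.000  -1.500  1.00  0.00           C
HETATM    5  O1  Q1C Q   4       0.000   0.000  23.500  1.00  0.00           O
END
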