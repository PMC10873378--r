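CCO
CC(=O)O.[Na+]
C[C@@H](N)C(=O)O
C1CCCCC1
CC
[Si](C)(C)C
CCN(CC)CC
OC[C@H](O)CN
C1CC1CO
N#CCC#N
CCOC(=O)CC(C)C
C(F)(F)F
CC(C)(C)OC(=O)N
invalid_smiles_line
ClCCCl
CCSCC
O=S(=O)(O)O
CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC
C[C@H]1CC[C@@H](N)CC1
OCC(O)CO
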