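# The 20 genetically coded amino acids, constitutional structures only
# (Kekule SMILES, no stereochemistry), three-letter codes.
NCC(=O)O Gly
NC(C)C(=O)O Ala
NC(C(C)C)C(=O)O Val
NC(CC(C)C)C(=O)O Leu
NC(C(C)CC)C(=O)O Ile
OC(=O)C1CCCN1 Pro
NC(CC1=CC=CC=C1)C(=O)O Phe
NC(CC1=CNC2=CC=CC=C12)C(=O)O Trp
NC(CCSC)C(=O)O Met
NC(CO)C(=O)O Ser
NC(C(O)C)C(=O)O Thr
NC(CS)C(=O)O Cys
NC(CC1=CC=C(O)C=C1)C(=O)O Tyr
NC(CC(=O)N)C(=O)O Asn
NC(CCC(=O)N)C(=O)O Gln
NC(CC(=O)O)C(=O)O Asp
NC(CCC(=O)O)C(=O)O Glu
NC(CCCCN)C(=O)O Lys
NC(CCCNC(=N)N)C(=O)O Arg
NC(CC1=CNC=N1)C(=O)O His
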