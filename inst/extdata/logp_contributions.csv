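# Atomic logP contributions by coarse atom-environment type.
# A deliberately coarse additive parameterization in the spirit of
# fragment/atom-contribution hydrophobicity schemes (Ghose & Crippen 1986,
# J. Comput. Chem. 7:565; Wildman & Crippen 1999, J. Chem. Inf. Comput.
# Sci. 39:868): each heavy atom contributes according to its element and
# immediate environment, with its hydrogens folded in. Values are chosen for
# internal consistency (alkane > ether > alcohol ordering, carbonyl and
# amine polarity) and are meaningful relative to one another within a
# library, not as absolute literature logP values.
# The placeholder B contributes 0: it marks an attachment point, not a group.
type,value,description
C_aliphatic,0.50,carbon with no heteroatom neighbours (hydrogens included)
C_hetero,0.15,carbon bonded to at least one N/O/S
C_carbonyl,-0.05,carbon double-bonded to oxygen
O_hydroxyl,-1.00,oxygen bearing at least one hydrogen
O_ether,-0.45,divalent oxygen with two heavy neighbours
O_carbonyl,-0.35,oxygen double-bonded to carbon
N_amine_H,-1.00,nitrogen bearing at least one hydrogen
N_amine_3,-0.65,fully substituted nitrogen
S_thio,0.25,divalent sulfur
B_placeholder,0.00,univalent attachment-point placeholder
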