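# Atomic van der Waals volumes (cubic Angstroms) from Bondi radii, used in
# the additive scheme of Zhao, Abraham & Zissimos (2003) J. Org. Chem.
# 68:7368: V_vdw = sum(atom contributions) - 5.92*N_bonds
#                 - 14.7*R_aromatic - 3.8*R_nonaromatic.
# The placeholder B is assigned the hydrogen contribution: it marks a bare
# attachment point, keeping volumes comparable across one placeholder-bearing
# formula space.
element,volume
H,7.24
C,20.58
N,15.60
O,14.71
S,24.43
B,7.24
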