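# Stability badlist for nucleoside-analogue enumeration (C/H/O spaces plus
# the univalent nucleobase placeholder B). A package reconstruction,
# documented pattern by pattern: the published lists it emulates are not
# reprinted here. The rules restrict the library to the saturated
# polyol/ether chemotype of the natural ribosides and to hydrolytically
# stable base attachments, on the argument that molecules must survive
# biochemically relevant aqueous conditions (moderate pH and temperature)
# and present cleanly reactive hydroxyls for polymerization:
#   - no O-O bonds;
#   - no carbonyl compounds: in a polyhydroxylated scaffold aldehydes,
#     ketones, acids and esters equilibrate with cyclic hemiacetals,
#     hydrates and lactols rather than existing as distinct stable isomers,
#     and they cross-react with backbone hydroxyls during polymerization;
#   - no carbonyl-precursor motifs (gem-diols, hemiacetals, orthoesters,
#     enols, ynol ethers, cumulenes);
#   - the base placeholder must sit on a saturated carbon carrying at most
#     one oxygen (the natural N-glycoside motif): B on oxygen is an N-O
#     bond, B on an alkene carbon is enamine-like, B on an O,O-acetal
#     carbon is an orthoamide-like centre - all hydrolytically labile.
# Per-pattern sensitivity of library counts can be tabulated with
# filter_library().
peroxide: O~O                # O-O bonds oxidatively/hydrolytically labile
gem_diol: [OH1]C[OH1]        # geminal diols are carbonyl hydrates
hemiacetal: [OH1]CO          # hemiacetals/hemiketals ring-open to carbonyls
orthoester: OC(O)O           # orthoesters hydrolyse stepwise
carbonyl: C=O                # no free carbonyl compounds (see header)
enol: C=C[OH1]               # enols tautomerize to carbonyls
ynol_ether: C#CO             # O on alkyne carbon: ketene-yielding tautomers
cumulene: *=C=*              # allenes/ketenes too reactive
base_on_oxygen: OB           # base-O link would be an N-O bond
base_on_alkene: C=CB         # N-vinyl attachment: enamine-like, labile
base_on_acetal: OC(B)O       # base on O,O-acetal carbon: orthoamide-like
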