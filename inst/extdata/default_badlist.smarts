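# Default chemical-plausibility badlist for exhaustive generation.
# A package reconstruction in the spirit of the forbidden-substructure lists
# used with orderly-generation programs to suppress molecules unstable under
# aqueous, biochemically relevant conditions. It is NOT a copy of any
# published list; each pattern documents its own rationale.
# Syntax: SMARTS subset, optional "name: " prefix, "#" comments.
peroxide: O~O              # O-O bonds: peroxides/dioxiranes, oxidatively labile
hydrazine: N~N             # N-N bonds: hydrazines/azo, redox-labile in water
hydroxylamine: N~O         # N-O bonds: hydroxylamines/oximes, hydrolytically labile
sulfenamide: S~N           # S-N bonds hydrolyse readily
sulfoxide_like: S~O        # S-O bonds outside fixed-valence model chemistry
disulfide: S~S             # S-S: monomer libraries keep the reduced thiol form
gem_diol: [OH1]C[OH1]      # geminal diols dehydrate to carbonyls
hemiacetal: [OH1]CO        # hemiacetals/hemiketals/carbinol ethers ring-open or hydrolyse
carbinolamine: [OH1]CN     # N,O on one sp3 carbon: dehydrates to imine
aminal: N[CH1]N            # geminal diamines hydrolyse to imines (guanidines, with no C-H, unaffected)
orthoester: OC(O)O         # three single-bonded O on one carbon hydrolyse stepwise
enol: C=C[OH1]             # enols tautomerize to carbonyls
enethiol: C=C[SH1]         # thio analogue of the enol rule
ynol: C#C[OH1]             # ynols are high-energy tautomers of ketenes
cumulene: *=C=*            # cumulated double bonds (allenes, ketenes) too reactive
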