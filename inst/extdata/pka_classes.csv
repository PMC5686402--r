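# Reference pKa values per ionizable-group class (side-chain context).
# Typical textbook values for free amino-acid side chains; the class lookup
# is the computation - no regression is attempted. Groups that are not
# appreciably ionizable in water (aliphatic hydroxyl, amide) yield NA.
class,pka
carboxyl,4.1
thiol,8.3
phenol,10.1
imidazole,6.0
guanidino,12.5
amine,10.7
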