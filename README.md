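# isogen

Exhaustive, non-redundant generation of constitutional isomers from
molecular formulae, and analysis of the virtual compound libraries this
makes possible. The package is aimed at chemical-space questions of the
kind asked in prebiotic chemistry and astrobiology: *of all the molecules a
formula permits, which are chemically plausible, and how special are the
ones biology actually uses?*

It provides, in one coherent toolchain:

* **A structure generator.** For an exact formula (or a *fuzzy* formula
  with per-element count ranges, e.g. `C2-6H0-13NO2-4`), `isogen`
  enumerates every connected molecular graph satisfying fixed Lewis
  valences (C 4, N 3, O 2, S 2, H 1) — each constitutional isomer exactly
  once. The engine is *orderly generation*: bond-order matrices are grown
  atom by atom and a structure is accepted only if it is the
  lexicographically maximal serialization within its isomorphism class, so
  completeness and non-redundancy hold by construction rather than by
  pairwise duplicate checks. A univalent placeholder atom (written `B`)
  marks the attachment point of a nucleobase-like recognition moiety.
* **Substructure filtering.** Badlists (forbidden substructures) and
  goodlists (required scaffolds) in a SMARTS subset, applied inside the
  generator with per-pattern removal accounting.
* **Library builders.** α-amino-acid libraries (exhaustive "UL" mode and a
  coded-alphabet-anchored "CL" mode) and nucleoside-analogue libraries
  (placeholder formula spaces, a stability badlist, and a minimum of two
  free O-H/N-H groups for polymerizability), plus symmetry-aware O→S
  substitution via automorphism orbits and certificate-based library
  comparison.
* **Descriptors and adaptive analysis.** Additive logP and van der Waals
  volume, rule-based side-chain pKa, Wiener index; and the
  adaptive-alphabet comparison, which asks how often a random same-size set
  of monomers covers those property axes with at least the *range* and
  *evenness* of a reference alphabet (e.g. the 20 coded amino acids).

The methods vignette (`vignettes/isomer-enumeration.Rmd`) documents the
model, the canonicity argument, the badlist rationales and the numerical
choices in detail.

## Worked example

Enumerate a formula and look at the run statistics:

```r
library(isogen)
mols <- enumerate_isomers("C2H6O")
vapply(mols, write_smiles, character(1))
#> [1] "COC"   "C(O)C"
attr(mols, "run")
#> <generation run> C2H6O: 2 emitted of 2 canonical structures (0 badlist,
#> 0 goodlist, 0 ring-size removals; 14 search nodes, 0 s)
```

Two structures: dimethyl ether and ethanol — the complete answer for
C2H6O. The same engine at scale builds the nucleoside-analogue library for
the natural riboside formula (B is the nucleobase placeholder):

```r
lib <- build_nucleoside_library("C5H9O4B")
lib
#> <library> nucleoside_analogues: 227 molecules
subset(lib$annotations, natural_riboside)$smiles
#> [1] "C(O)(C1O)C(OC1B)CO"
```

Of 32 710 raw constitutional isomers of C5H9O4B, the shipped stability
badlist (no O–O bonds, no carbonyls or their precursor motifs, no labile
base attachments) removes 32 398, and the requirement of at least two free
hydroxyl/amine sites removes another 85, leaving **227** candidate
monomers — among them, flagged, the natural β-ribofuranoside connectivity.

Descriptors for the coded amino-acid alphabet:

```r
pt <- property_table(new_library(coded_amino_acids(), name = "coded20"))
head(pt[, c("smiles", "logp", "vdw_volume", "pka", "wiener")], 5)
#>                          smiles  logp vdw_volume  pka wiener
#>  NC(C(O)=O)CC(C1=2)=CNC1=CC=CC2  0.55     189.62   NA    369
#>        NC(C(O)=O)CC(C=1)=CC=CC1  1.25     159.02   NA    212
#>     NC(C(O)=O)CC(C=1)=CC=C(C1)O -0.10     167.81 10.1    268
#>            NC(C(O)=O)CCCNC(N)=N -3.95     168.66 12.5    247
#>          NC(C(O)=O)CC(N=1)=CNC1 -2.95     142.66  6.0    165
```

(Rows are certificate-ordered: tryptophan, phenylalanine, tyrosine,
arginine, histidine. `NA` pKa means a non-ionizable side chain.)

A command-line wrapper ships in `inst/cli/isogen`:

```sh
Rscript inst/cli/isogen generate --formula C2H6O --count-only   # prints 2
Rscript inst/cli/isogen library nucleosides --space C5H9O4B --out lib.smi
```

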