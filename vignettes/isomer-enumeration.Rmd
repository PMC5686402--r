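---
title: "Orderly generation of constitutional isomers and chemical-space analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orderly generation of constitutional isomers and chemical-space analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isogen)
```

## The model

A molecule is represented as a connected multigraph: nodes are heavy atoms
labeled with an element symbol, edges are covalent bonds of order 1, 2 or 3.
Every element has one fixed valence — C 4, N 3, O 2, S 2, H 1 — and each
atom implicitly carries as many hydrogens as its valence leaves unused.
Charges, radicals, hypervalent states and stereochemistry are outside the
model; sulfur is divalent only, so every oxygen position of any generated
molecule can be exchanged for sulfur without revisiting valence bookkeeping.

The symbol `B` does not denote boron: it is a univalent placeholder marking
the attachment point of a recognition moiety (in the nucleoside application,
a nucleobase). Treating the base as a single univalent pseudo-atom makes the
enumeration of base-carrying scaffolds tractable — the placeholder
participates in exactly one single bond — and the actual base can be
substituted afterwards.

Two molecules are the same constitutional isomer exactly when their graphs
are isomorphic (same atoms, same bonds, same orders). This is a
Kekulé-level identity: benzene is stored with explicit alternating bonds,
and the two Kekulé assignments of a ring are one isomer precisely because
they are isomorphic graphs. No aromaticity normalization pass is applied by
default; for every library built here the identification is exact because
isomorphism, not bond-assignment syntax, is what is compared.

## Certificates and orderly generation

Deduplication needs a canonical form. Atoms are ordered by decreasing
valence, then element symbol; the *certificate* of a graph is the
lexicographically maximal column-major upper-triangle serialization of its
bond-order matrix over all element-preserving atom permutations, found by
backtracking with prefix pruning. Isomorphic graphs have identical
certificates and non-isomorphic ones differ, which the test suite verifies
against exhaustive permutation search and thousands of random relabelings.

The generator builds bond-order matrices atom by atom: when atom *k* is
added, its bonds to atoms 1..k−1 are chosen subject to residual valences,
the total bond-order budget implied by the hydrogen count, and connectivity
feasibility. A completed matrix is accepted only if it *is* its own
certificate serialization. Because a column-major prefix of the
serialization is exactly the serialization of the induced subgraph on the
first *k* atoms, a partial structure whose prefix can be improved by
transposing two same-element atoms can be pruned immediately: no canonical
completion can grow from it. This is orderly generation — every isomorphism
class is emitted exactly once, with no pairwise duplicate comparisons and
no global duplicate cache.

Two independent checks guard the engine. A plain brute-force enumerator
fills every cell of the bond-order matrix with no canonicity logic,
keeps connected graphs and deduplicates by certificate; the suite sweeps
*all* C/N/O/S/B formulae with up to five heavy atoms and requires exact
certificate-set equality. And classic counts are pinned: 2 butanes,
5 hexanes, 9 heptanes, 3 isomers of C2H4O, 217 constitutional isomers
of C6H6.

Constraints (forbidden substructures, required substructures) are applied at
emission, inside the compiled search. Filtering at emission makes
"generate with constraints" provably equal to "generate, then filter",
which is asserted in the tests, and the per-pattern removal counts reported
in each `generation_run` always balance the unconstrained total.

## Formulae, fuzzy formulae, graphicality

`parse_formula()` accepts exact formulae (`"C5H9O4B"`) and fuzzy formulae
with per-element ranges (`"C2-6H0-13NO2-4"`). Fuzzy expansion takes the
Cartesian product of ranges and keeps the *graphical* combinations — those
realizable as a connected multigraph under the valence model: even valence
sum, non-negative degree of unsaturation, enough bonds to connect all heavy
atoms, a feasible degree sequence, and (for diatomics) the bond-order cap.
The predicate is tested exhaustively against the generator: on every small
formula, `is_graphical` is true exactly when at least one structure exists.

When hydrogen is omitted from a fuzzy formula it is *free*: every hydrogen
count achievable by valence closure is expanded. This is the default mode
for placeholder spaces, where writing the hydrogen index explicitly per
carbon number is error-prone; valence closure determines the admissible
counts anyway. Expansion is capped (default 10 000 formulae) so a typo
cannot silently schedule a combinatorial explosion.

## Badlists

Exhaustive generation deliberately produces everything Lewis-valid, so
chemically implausible output must be suppressed by explicit, documented
rules. Patterns use a SMARTS subset (elements, wildcard `*`, bond symbols
`- = # ~`, branches, rings, and `[XHn]` for "at least n hydrogens"), and a
badlist file carries one pattern per line with its rationale as a comment.

Two lists ship with the package, and both are *package reconstructions*:
the corresponding lists used in the original virtual-library studies are
published in companion supplements and are not reproduced here. Each
pattern is therefore individually documented and the effect of every
pattern on any library is measurable (`filter_library()` reports
per-pattern removals under first-match attribution, and every
`generation_run` records the same accounting), so the sensitivity of a
library size to any single rule can be tabulated.

The *plausibility* list (`default_badlist()`) removes heteroatom–heteroatom
bonds (O–O, N–N, N–O, S–N, S–O, S–S), carbonyl-precursor motifs (geminal
diols, hemiacetals, carbinolamines, aminals, orthoesters, enols, enethiols,
ynols) and cumulated double bonds.

The *nucleoside stability* list (`nucleoside_stability_badlist()`) encodes
the stricter demand that a nucleoside-analogue monomer survive aqueous
biochemical conditions and present cleanly reactive hydroxyls for
polymerization. Its strongest rule excludes all free carbonyl compounds:
in a polyhydroxylated scaffold, aldehydes, ketones, acids and esters
equilibrate with cyclic hemiacetals, lactols and hydrates rather than
persisting as distinct stable isomers, and they cross-react with backbone
hydroxyls during polymerization. Together with the carbonyl-precursor
rules this restricts the library to the saturated polyol/ether chemotype of
the natural ribosides. Three rules govern the base attachment: the
placeholder may not sit on oxygen (an N–O bond), on an alkene carbon
(enamine-like) or on an O,O-acetal carbon (orthoamide-like); the natural
N-glycosidic motif — base on a saturated carbon bearing at most one
oxygen — passes.

## The nucleoside-analogue library

`build_nucleoside_library()` enumerates a placeholder formula space
(every expansion must contain exactly one `B`), applies the stability
badlist during generation, and then keeps molecules with at least two
*free functional groups*: oxygen or nitrogen atoms carrying at least one
hydrogen and not bonded to the placeholder. Two such sites are the minimum
for a monomer to be incorporated into a linear polymer; sites on the
attachment carbon's substituents count, the placeholder's own neighbor
does not. Counting sites (atoms), not hydrogens, is deliberate: a primary
amine is one attachment site.

For the natural riboside formula C5H9O4B the pipeline computes, at run
time: 32 710 raw constitutional isomers, of which the stability badlist
removes 32 398 and the two-functional-group rule a further 85, leaving
**227** analogues. The member with the natural β-ribofuranoside
connectivity (`OCC1OC(B)C(O)C1O`, stereochemistry being outside the model)
is present and flagged in the library annotations.

## The α-amino-acid libraries

`build_amino_acid_library()` requires every member to carry the α-amino-acid
scaffold — an amino nitrogen with at least one N–H bonded to an α-carbon
bearing at least one hydrogen, bonded to a carboxyl group — expressed as the
goodlist pattern `[NH1][CH1]C(=O)[OH1]`. N-substituted (proline-like)
scaffolds are matched by the same pattern when the ring nitrogen retains one
hydrogen; a config flag relaxes the N–H requirement entirely for fully
N-substituted designs.

The "unique library" (UL) mode covers a formula space exhaustively:
carbon 2..max crossed with nitrogen and oxygen ranges, hydrogen free.
The default ranges (N 1–2, O 2–3) bracket the scaffold's own requirement
(N1 O2) with one extra heteroatom of headroom each; they are a design
choice balancing coverage against the combinatorial growth of the space,
and both ranges are arguments. The "combined library" (CL) mode reuses the
exhaustive construction and additionally injects the 20 genetically coded
amino acids (their constitutional structures ship with the package) up to
the carbon bound, anchoring the library to the coded alphabet. The
published UL/CL sizes (121 044 at six carbons; 3 846) depend on the
original 156-pattern badlist from a companion supplement and are treated as
stretch targets, not test expectations; the suite instead asserts the
properties that do not depend on badlist composition — monotone growth in
the carbon bound, 100 % scaffold coverage, duplicate-freeness, and
glycine's presence.

## Symmetry-aware heteroatom substitution

Divalent O can be exchanged for divalent S without re-running the
generator, but naive position-by-position replacement overcounts whenever
positions are symmetry-equivalent (ethylene glycol has two oxygens and one
mono-thio product). `substitute_heteroatom()` computes each molecule's
automorphism group and emits one product per *orbit* of oxygen-position
subsets, then deduplicates across the library by certificate. The suite
verifies the library-level identity: substituting every C2H6O2 isomer
equals de-novo enumeration of C2H6OS, certificate for certificate.

## Descriptors

Three axes drive the adaptive analysis, all deterministic and
permutation-invariant, with parameter tables shipped as commented CSV files:

* **logP** — additive atomic contributions over coarse environment types
  (aliphatic/heteroatom-substituted/carbonyl carbon; hydroxyl, ether,
  carbonyl oxygen; N–H vs substituted nitrogen; sulfur). The values are a
  deliberately coarse re-parameterization in the spirit of published
  atom-contribution hydrophobicity schemes; they order chemotypes sensibly
  (alkane above ether above alcohol) and are meaningful *relative to one
  another*, not as absolute literature logP values. The tests pin the table
  by recomputing molecules by hand from it.
* **van der Waals volume** — the additive scheme of Zhao, Abraham &
  Zissimos (2003): Bondi atomic volumes minus 5.92 Å³ per bond and ring
  corrections (14.7 aromatic, 3.8 otherwise). The placeholder takes the
  hydrogen volume, marking a bare attachment point. One consequence is
  worth stating plainly: within a single-formula library all members share
  the atomic sum, so volumes separate only by ring count. In the C5H9O4B
  library every surviving isomer is monocyclic and all 227 volumes tie at
  the minimum; the "natural riboside is among the most compact" statement
  therefore holds in the degenerate rank sense (nothing is strictly
  smaller), and a finer, conformer-aware volume would be needed to resolve
  the tie. The test asserts the rank property (fewer than 10 % strictly
  smaller), which is what an additive scheme can honestly support.
* **pKa** — a rule-based class lookup, not a regression: the side chain
  (everything outside the scaffold match) is classified by substructure
  priority (carboxyl, thiol, phenol, imidazole, guanidino, amine, with
  amide N–H excluded from the amine class) and mapped to a reference value;
  non-ionizable side chains (glycine's hydrogen, aliphatic hydroxyls)
  yield `NA`.

The Wiener index (sum of all-pairs topological distances) is computed via
shortest paths and checked against an independent BFS oracle on random
graphs.

## Adaptive-alphabet analysis

A candidate set of monomers is *better* than a reference set if, on every
property axis, its range (max − min) and its evenness are both at least the
reference's, with strict improvement somewhere. No formula for evenness is
standard, so the package defines and documents one: for the gaps between
consecutive sorted values, evenness = 1 − CV/√(m−1), where CV is the
population coefficient of variation of the m gaps and √(m−1) is the CV of
the most uneven arrangement (everything in one gap). It is 1 for perfect
spacing, 0 for the one-gap extreme, invariant under affine transforms of
the axis, and clipped to [0, 1]. The metric sits behind a single function
(`evenness()`) so alternates (nearest-neighbor, entropy-based) can be
swapped for sensitivity analysis. Members with `NA` on an axis (pKa) are
excluded from that axis's statistics, with the resolved count reported —
the package takes no stance on how non-ionizable members "should" enter a
pKa axis, it simply reports how many were used.

`sample_random_sets()` draws uniform without-replacement sets and counts
better ones; everything is determined by the seed. The planted-dominance
fixture makes the Monte-Carlo estimate checkable against an *exact* value:
a 24-molecule library whose reference (19 identical values plus one
outlier: range 10, evenness exactly 0 on every axis) is beaten precisely by
sets containing one of two range-extending "supers", so the exact better
fraction is 1 − C(22,2)/C(24,4) ≈ 0.9783, also recomputed by complete
enumeration of all 10 626 subsets. The suite requires the Monte-Carlo
fraction at n = 10 000 to fall within three standard errors of it. The
fixture is a correctness instrument: it deliberately makes better sets
common, which says nothing about their rarity in real libraries.

An energetic-cost comparison (mean heat of formation of candidate vs
reference) is supported only through the external-column hook of
`property_table()`; no quantum chemistry is attempted in this package.

## Numerical and engineering choices

* Emission order is lexicographic by certificate; two runs with identical
  inputs are byte-identical, and every library is keyed and sorted by
  certificate.
* The generator and the matcher are compiled (Rcpp); the brute-force oracle
  is a separate plain algorithm. Generation caps (`max_emit`, default
  2·10⁶) and the fuzzy-expansion cap turn runaway inputs into errors, not
  hangs.
* Ring-size constraints are applied post hoc via shortest-cycle analysis;
  a double bond is not a two-ring.
* Problem sizes in the test suite are chosen for exhaustiveness where it is
  cheap (all ≤5-heavy-atom formulae against the oracle, ~6 000+ structures)
  and for single-run determinism where it is not (the C5H9O4B space,
  32 710 structures, is enumerated twice in the suite).

## Limitations

* No stereochemistry: all counts are constitutional; stereoisomer counts
  would be larger by the symmetry-dependent factors discussed in the
  library annotations' source literature.
* No charges, radicals, tautomer merging or aromatic perception beyond
  alternating six-membered carbocycles (used only for the volume ring
  correction).
* Badlists are reconstructions; library sizes that depend on unpublished
  pattern lists are reproducible *under the shipped, documented lists*, and
  the per-pattern accounting exists precisely so that any alternative list
  can be evaluated transparently.
* Descriptor values are internally consistent but not calibrated to
  experimental scales; rankings within a library are the supported use.
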