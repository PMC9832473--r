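---
title: "How pepiso computes isoelectric points of modified peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How pepiso computes isoelectric points of modified peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepiso)
```

## The model

`pepiso` treats a peptide as a collection of independent acid/base
equilibria. Each basic group contributes `1/(1 + 10^(pH - pKa))` to the net
charge, each acidic group `-1/(1 + 10^(pKa - pH))`, and permanently ionized
groups add a pH-independent `Q_constant`. The isoelectric point is the root
of the resulting monotone non-increasing charge curve on pH 0–14.

The independence assumption is the model's central approximation: the
ionization state of one group is taken not to influence any other. That is
accurate for well-separated sites and increasingly wrong for adjacent ones
(salt bridges, hydrogen-bonded pairs, perturbed microenvironments in a
fold). No microstate enumeration and no 3D/conformational correction is
attempted; what the published pKa sets learned from their training data is
the only way such effects enter.

## Finding the ionizable groups in a structure

**Fragmentation.** All secondary and tertiary amide bonds are cleaved. The
cleavable pattern is the C(=O)–N single bond where the carbonyl carbon's
third substituent is carbon (this excludes ureas, carbamates and
formamides) and the nitrogen carries at least one carbon besides the acyl
group (this excludes primary amides: Asn/Gln side chains and C-terminal
carboxamides stay intact). Freed amines are capped with acetyl, freed
carbonyl carbons with a methyl group, so each fragment keeps the strongly
electron-withdrawing backbone environment that shifts side-chain pKa
values.

Two boundary policies are our own decisions, since "cut all peptide bonds"
does not define them:

* *Ring amides.* Lactams in rings of seven atoms or fewer (pyroglutamate,
  diketopiperazines) are left closed — opening them would invent chemistry
  the molecule does not have — while amide bonds in larger rings
  (head-to-tail macrocyclic peptides) are cleaved, so a cyclic n-mer yields
  n fragments.
* *Caps are remembered.* Cap atoms are flagged, and bonds involving them
  are never re-cleaved, which makes fragmentation idempotent on its own
  output. A genuine N-acetyl terminus arriving in fresh input is cut like
  any other amide and immediately re-capped with acetyl; the net effect is
  the same fragment plus an inert three-carbon leftover.

Disulfide bonds are not cleaved: a cystine pair travels as a single
two-backbone fragment, which no canonical template matches, and since the
oxidized sulfur has no proton, no thiol rule fires — the bridge correctly
contributes nothing.

**Canonical matching.** Each capped fragment is matched against templates
of the 20 canonical residues written in the package's SMARTS subset
(`extdata/canonical_templates.tsv`). A match is accepted only if it covers
every heavy atom of the fragment apart from the caps and the single
C-terminal substituent (OH of a free acid or NH2 of a primary
carboxamide), so partial resemblance is not enough: an N-methylated or
β-homologated residue fails coverage and is routed to the rule engine.
Caps are recognized structurally (an acetyl on nitrogen, a terminal methyl
on the carbonyl), so fragments read from files match exactly like
fragments the cleaver produced.

Tautomeric and ionization forms: fragments are first *neutralized* —
protonated sp3 amines, deprotonated carboxylates/phenolates/thiolates and
amide anions are set to their neutral reference forms (bonded charge pairs
such as nitro groups, and hydrogen-free quaternary nitrogens, are left as
drawn). Centers that neutralization cannot canonicalize keep explicit
template variants: both neutral histidine tautomers plus imidazolium, and
neutral plus protonated guanidine for arginine. A free amino acid — both
termini ionizable, no caps — deliberately matches nothing and is handled
entirely by the rule engine, mirroring the reference workflow.

Position classes fall out of the cap pattern: a fragment with a free
α-amine is `n_terminal`, a free acid/amide end is `c_terminal`, both
capped is `internal`. These drive the position-dependent pKa sets.

## The pKa knowledge

Eight published canonical sets ship in `extdata/pka_sets.tsv` (one
documented row per value; user files in the same format can be supplied).
Six sets are the nine printed values each. Two families are richer:

* *Gauci* (extended-Bjellqvist lineage) varies the terminus pKa with the
  terminal residue type.
* *ProMoST* varies both termini per residue and the seven ionizable side
  chains by position (N-terminal / internal / C-terminal).

The per-residue and positional values of these two sets are not printed in
the primary literature table; the shipped numbers are transcribed from the
publicly available pIR/ProMoST lineage and are marked as externally derived
in the data file. The package's tests pin them only to the published
ranges (e.g. Gauci N-terminus within 6.50–8.36). Lehninger terminus values
are the published averaged-over-residues numbers, as printed.

**Admissibility window.** Predicted pKa values only enter the charge model
if acids lie in [-5, 12) and bases in (2, 15]. The primary bounds follow
the "acids below 12, bases above 2" convention (we read *below*/*above* as
strict); the outer guards are inclusive and exist to keep strong but real
groups — sulfates near -3, guanidines near 13 — in the calculation while
discarding centers that only ionize at experimentally meaningless pH
(aliphatic alcohols around 14).

## Rule-based pKa prediction

`extdata/pka_rules.tsv` holds an ordered table of ~30 substructure rules,
each with one or two ionizable centers (a phosphate contributes two
equilibria). Order is the precedence: for every rule, in file order, and
every distinct match, a center claims its atom unless an earlier rule, a
canonical match, or a permanent-charge center already claimed it. Claiming
happens even when the value then fails the admissibility window — the atom
has been recognized; it is simply not ionizable in range.

The table follows the Dimorphite-DL-derived starting point with the
adjustments the method calls for: overly generic aromatic-nitrogen and
bare amine patterns replaced by specific ones (α-amino-acid amines before
generic amines, anilines separate from alkylamines), medicinal-chemistry
groups added (tetrazole, imidazole, substituted phenols, sulfonamides,
hydroxamic acids), and amide/sulfonamide/iminium nitrogens excluded from
the amine rules via recursive-pattern guards. Values are representative
group means; correctness is defined behaviorally (the chemistry panel in
the test suite checks counts and types per functional group), not by
string identity with any external rule list. Symmetric matches are
canonicalized by sorted atom assignment, so results are deterministic and
symmetric duplicates collapse at the claim step.

Permanent charges: four-valent, hydrogen-free nitrogens (quaternary
ammonium, N-alkyl pyridinium) add +1 each to `Q_constant`. Nothing else is
treated as constantly ionized.

## Numerics

* **pI.** Bisection on [0, 14], interval-width convergence 1e-6 with a
  200-iteration cap; a result is `defined` when the converged root meets
  the published 0.01 e charge tolerance. The tight width criterion (rather
  than stopping at the first |Q| ≤ 0.01) keeps the root within 0.01 pH of
  a dense-grid reference even on flat curves.
* **Undefined cases.** If Q has one sign on the whole interval, the curve
  is scanned on a 0.01 grid and the minimum refined: |Q|min ≤ 0.05 e is
  reported as `asymptotic_touch` at the pH of closest approach, otherwise
  `no_crossing` (only acids, only bases, net permanent charge).
* **Isoelectric interval.** The maximal span with −0.05 ≤ Q ≤ 0.05,
  located by root-bracketing on the band edges (monotonicity makes the
  edges unique); undefined when the curve never enters the band.
* **Consensus.** The mean and *population* standard deviation are taken
  over the sets with a defined pI; undefined sets are excluded and
  flagged. All eight shipped sets participate by default (the source
  material does not say whether a subset was used; a `sets` argument
  exposes the choice). The charge at the reporting pH (default 7.4) is
  given per set and as a mean, and the top-level isoelectric interval is
  the mean of the per-set edges — the per-set values are in the tidy
  output whenever the aggregation is too coarse.

Rule-predicted groups are identical across sets, so a molecule whose every
ionizable group is noncanonical has zero consensus spread by construction.

## Sequence mode

`sequence_consensus()` applies the same solver to groups read from a
one-letter sequence: both termini ionizable, one group per C/Y/D/E/H/K/R
side chain, position-dependent values where a set provides them, and
nothing for `X`. Lower-case letters are upper-cased on input (automated
structure-to-sequence exports sometimes mark modified residues by case;
side-chain pKa in this model is chirality-independent, so folding case is
the conservative reading). A single-letter sequence takes its N-terminal
values for the N-terminus and C-terminal values for the C-terminus.

The strongest internal consistency check ties the two modes together: for
random all-canonical peptides with free termini, per-set structure-mode and
sequence-mode pI agree within 0.01 pH. The test suite runs this for 50
random peptides of length 2–15 under a fixed seed.

## The synthetic peptide builder

Test structures are assembled from templated monomer graphs joined through
amide bonds — never by string concatenation — so every atom is accounted
for. The builder covers the modification chemistry of the validation
domain: N-methylation, β-homologation, lysine quaternization, disulfide
bridges, N-terminal acetylation and pyroglutamate, C-terminal amidation.
Histidine is built as the Nε-H tautomer and arginine as neutral guanidine;
the matcher's variant templates make these choices invisible.

What the builder does *not* emulate — and therefore what passing tests do
not show — matters: no stereochemistry (pI is stereo-independent in this
model), no esters/depsipeptides, no conjugated dyes or PEGylation, no
genuinely exotic scaffolds. Rule-engine behaviour on such chemistry is
exercised only by the hand-written SMILES panel, and real-world accuracy
on heavily modified peptides ultimately depends on the rule table's
coverage, which is deliberately auditable and extensible as a plain-text
file.

## Known limitations

* Independent-site Henderson–Hasselbalch: no coupling between neighbouring
  centers, no tautomer populations, no conformational effects.
* The rule table is a compact reconstruction (~30 rules); rare ionizable
  groups absent from it contribute nothing to the charge model.
* Gauci/ProMoST positional values are transcriptions of public resources,
  pinned by tests only to their published ranges.
* Aromaticity perception is a pragmatic per-ring Hückel count (with a
  fused-ring allowance); it covers the heteroaromatics the templates and
  rules use, not arbitrary polycyclic systems.
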