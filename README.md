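# pepiso

Structure-based isoelectric point (pI) calculation for natural and chemically
modified peptides.

## Why

The pI — the pH at which a molecule carries no net charge — drives peptide
solubility, aggregation and chromatographic behaviour, so purification and
design teams lean on calculated pI values constantly. Conventional
calculators read a one-letter sequence, which silently ignores everything a
medicinal chemist actually does to a peptide: C-terminal amidation,
N-terminal acetylation or pyroglutamate, N-methylation, β-amino acids,
disulfide bridges, quaternized side chains, dye conjugates. `pepiso` computes
pI from the *chemical structure* instead, so those modifications change the
answer the way they change the molecule.

## Method

For a structure (SMILES or SDF):

1. **Fragmentation.** Every secondary and tertiary backbone amide bond is
   cleaved; freed amines are capped with acetyl and freed carbonyls with
   methyl (methyl ketone), preserving the electron-withdrawing backbone
   environment. Primary amides (Asn/Gln side chains, C-terminal
   carboxamides) and small-ring lactams (pyroglutamate) are never cut.
2. **Canonical matching.** Each capped fragment is compared against
   substructure templates of the 20 canonical residues (explicit tautomers
   and ionization forms) plus ionizable N-termini and conventional
   C-termini. Matched groups take their pKa from a chosen published set;
   eight sets are shipped (IPC_peptide, IPC2_peptide, Gauci, Grimsley,
   Toseland, Thurlkill, Lehninger, ProMoST — the latter two families with
   per-residue/position-dependent terminus values).
3. **Rule-based pKa prediction.** Fragments that are not canonical residues
   run through an ordered, first-match-wins table of substructure rules
   (carboxylic acids, phenols, thiols, amines, imidazoles, tetrazoles,
   phosphates, ...). Each rule tracks which atom is ionizable; an atom
   claimed by one rule is never re-assigned. Predicted acids must have
   pKa in [-5, 12) and bases in (2, 15] to enter the model. Four-valent
   nitrogens (quaternary ammonium, N-alkyl pyridinium) contribute a
   permanent charge Q_constant instead.
4. **Charge model and pI.** Net charge is the independent-site
   Henderson–Hasselbalch sum

   Q(pH) = Σ_bases 1/(1+10^(pH−pKa)) − Σ_acids 1/(1+10^(pKa−pH)) + Q_constant

   and pI solves Q(pH) = 0 by bisection on pH 0–14 with a charge tolerance
   of 0.01 e. Curves that never cross zero are classified (`no_crossing`,
   or `asymptotic_touch` when |Q| still dips below 0.05 e), and the
   *isoelectric interval* — the pH span with |Q| ≤ 0.05 e — characterizes
   flat curves. Results are reported per pKa set and as a consensus
   mean ± SD.

A sequence mode (`sequence_consensus()`, FASTA input supported) applies the
identical charge machinery to one-letter sequences, ignoring the side chains
of noncanonical residues written `X` — useful mainly to quantify what
structure awareness buys you.

## Worked example

His-Gly from SMILES:

```r
library(pepiso)
res <- pi_consensus("NC(Cc1c[nH]cn1)C(=O)NCC(=O)O")  # His-Gly
res
#> <pi_result> structure mode, input: NC(Cc1c[nH]cn1)C(=O)NCC(=O)O
#>   pI = 7.20 +/- 0.55 (over 8 of 8 pKa sets)
#>   isoelectric interval (|Q| <= 0.05 e): 6.97 - 7.42
#>   net charge at pH 7.4: -0.17 e
tidy(res)[, c("set", "pi", "q_at_ph")]
#> # A tibble: 8 × 3
#>   set             pi q_at_ph
#> 1 IPC_peptide   7.79  0.0330
#> 2 IPC2_peptide  7.19 -0.122
#> 3 Gauci         6.74 -0.406
#> 4 Grimsley      7.15 -0.197
#> 5 Toseland      7.52  0.0318
#> 6 Thurlkill     7.27 -0.0793
#> 7 Lehninger     7.85  0.0332
#> 8 ProMoST       6.05 -0.621
```

The per-set spread (±0.55 here) is the uncertainty carried by the choice of
published pKa set. `autoplot(res)` draws the charge-versus-pH curves with the
per-set pI marked; `glance(res)` gives the one-row summary.

Why structure matters: LHRH (pGlu-His-Trp-Ser-Tyr-Gly-Leu-Arg-Pro-Gly-NH2)
and its C-terminal free-acid analogue share the same letter sequence, but

```r
amide <- pi_consensus(build_structure(
  peptide_spec("QHWSYGLRPG", nterm = "pyroglutamate", cterm = "primary_amide")))
acid  <- pi_consensus(build_structure(
  peptide_spec("QHWSYGLRPG", nterm = "pyroglutamate", cterm = "acid")))
abs(amide$pi_mean - acid$pi_mean)
#> [1] 2.935609
```

— a ~2.9 pH-unit separation a sequence calculator reports as exactly zero.

Batch use is data-frame-first and pipe-friendly:

```r
read_smiles_file("peptides.smi") |> pi_structures(smiles, id = id) |>
  write_results("results.csv")
```

and a command-line front end is installed at `exec/pepiso`
(`pepiso pi --input peptides.smi --out results.csv --plot curves_%s.png`).

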