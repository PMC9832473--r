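test_that("all twenty capped residues round-trip through their templates", {
  ionizable <- c("C", "Y", "D", "E", "H", "K", "R")
  for (r in pepiso:::.AA_LETTERS) {
    mm <- match_canonical(capped_fragment(r))
    expect_true(nrow(mm) >= 1L, info = r)
    expect_identical(mm$residue[1], r, info = r)
    expect_identical(mm$kind[1], "sidechain", info = r)
    expect_identical(mm$position_class[1], "internal", info = r)
    if (r %in% ionizable) {
      expect_false(is.na(mm$atom_frag[1]), info = r)
    } else {
      expect_true(is.na(mm$atom_frag[1]), info = r)
    }
  }
})

test_that("terminal fragments report their position class and terminus matches", {
  frags <- cleave_and_cap(build_structure("KAD"))
  m1 <- match_canonical(frags[[1]])
  expect_setequal(m1$kind, c("sidechain", "nterm_amine"))
  expect_true(all(m1$position_class == "n_terminal"))
  m3 <- match_canonical(frags[[3]])
  expect_setequal(m3$kind, c("sidechain", "cterm_acid"))
  expect_true(all(m3$position_class == "c_terminal"))
  # primary carboxamide terminus is recognized but non-ionizable
  frags_am <- cleave_and_cap(build_structure(peptide_spec("KAD", cterm = "primary_amide")))
  m3a <- match_canonical(frags_am[[3]])
  expect_true("cterm_primary_amide" %in% m3a$kind)
  g <- assign_canonical_pkas(m3a, get_pka_set("IPC_peptide"))
  expect_false(any(grepl("C-terminus", g$label)))
})

test_that("ionization and tautomeric forms of the same residue match identically", {
  # internal His fragment drawn four ways
  forms <- c(
    "CC(=O)NC(Cc1c[nH]cn1)C(C)=O",      # N-delta-H tautomer
    "CC(=O)NC(Cc1cnc[nH]1)C(C)=O",      # N-epsilon-H tautomer
    "CC(=O)NC(Cc1c[nH]c[nH+]1)C(C)=O"   # imidazolium
  )
  for (smi in forms) {
    mm <- match_canonical(mol_from_smiles(smi))
    expect_identical(mm$residue, "H", info = smi)
    expect_identical(mm$kind, "sidechain", info = smi)
  }
  # carboxylate versus carboxylic acid on an aspartate fragment
  acid <- match_canonical(mol_from_smiles("CC(=O)NC(CC(=O)O)C(C)=O"))
  carbox <- match_canonical(mol_from_smiles("CC(=O)NC(CC(=O)[O-])C(C)=O"))
  expect_identical(acid$residue, carbox$residue)
  expect_identical(acid$kind, carbox$kind)
})

test_that("backbone modifications and lone amino acids are routed to the predictor", {
  # N-methylation breaks the canonical template
  frags <- cleave_and_cap(build_structure(peptide_spec(
    "AH", modifications = list(list(position = 2L, kind = "n_methyl")))))
  expect_identical(nrow(match_canonical(frags[[2]])), 0L)
  # a free amino acid (both termini ionized) is deliberately not canonical
  expect_identical(nrow(match_canonical(cleave_and_cap(build_structure("H"))[[1]])), 0L)
  # cystine: the disulfide-bonded pair is not a free-thiol Cys
  m <- build_structure(peptide_spec("GCGCG", modifications = list(
    list(position = c(2L, 4L), kind = "disulfide_pair"))))
  frags2 <- cleave_and_cap(m)
  bridged <- frags2[[which(vapply(frags2, function(f) sum(f$atoms$element == "S") == 2L, logical(1)))]]
  expect_identical(nrow(match_canonical(bridged)), 0L)
  # ...and with both backbones capped, the oxidized sulfurs contribute nothing
  expect_identical(nrow(predict_pkas(bridged)), 0L)
})

test_that("canonical pKa assignment consults set, residue and position", {
  h <- match_canonical(capped_fragment("H"))
  g <- assign_canonical_pkas(h, get_pka_set("IPC_peptide"))
  expect_equal(g$pka, 6.018)
  expect_identical(g$eq_type, "base")

  frags <- cleave_and_cap(build_structure("GD"))
  gn <- assign_canonical_pkas(match_canonical(frags[[1]]), get_pka_set("Thurlkill"))
  expect_equal(gn$pka[grepl("N-terminus", gn$label)], 8.0)

  # ProMoST: D side chain at the N-terminal position
  frags2 <- cleave_and_cap(build_structure("DG"))
  gp <- assign_canonical_pkas(match_canonical(frags2[[1]]), get_pka_set("ProMoST"))
  expect_equal(gp$pka[grepl("sidechain", gp$label)], 3.57)
  # Gauci: per-residue N-terminus value for proline
  frags3 <- cleave_and_cap(build_structure("PG"))
  gg <- assign_canonical_pkas(match_canonical(frags3[[1]]), get_pka_set("Gauci"))
  expect_equal(gg$pka[grepl("N-terminus", gg$label)], 8.36)
})

test_that("no atom is the ionizable atom of two matches", {
  for (seq in c("DHKC", "YRGE")) {
    frags <- cleave_and_cap(build_structure(seq))
    atoms <- unlist(lapply(frags, function(f) {
      mm <- match_canonical(f)
      mm$atom[!is.na(mm$atom)]
    }))
    expect_identical(anyDuplicated(atoms), 0L, info = seq)
  }
})
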