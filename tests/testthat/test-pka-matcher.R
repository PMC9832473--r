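test_that("the rule engine emits the expected group counts over the chemistry panel", {
  panel <- rule_panel()
  for (i in seq_len(nrow(panel))) {
    frag <- cleave_and_cap(mol_from_smiles(panel$smiles[i], name = panel$name[i]))[[1]]
    g <- predict_pkas(frag)
    expect_identical(sum(g$eq_type == "acid"), panel$acids[i], info = panel$name[i])
    expect_identical(sum(g$eq_type == "base"), panel$bases[i], info = panel$name[i])
  }
})

test_that("every emitted pKa respects the admissibility window", {
  panel <- rule_panel()
  groups <- dplyr::bind_rows(lapply(panel$smiles, function(s) {
    predict_pkas(cleave_and_cap(mol_from_smiles(s))[[1]])
  }))
  acids <- groups$pka[groups$eq_type == "acid"]
  bases <- groups$pka[groups$eq_type == "base"]
  expect_true(all(acids >= -5 & acids < 12))
  expect_true(all(bases > 2 & bases <= 15))
})

test_that("multi-center rules add two equilibria; symmetric matches are not double counted", {
  g <- predict_pkas(mol_from_smiles("COP(=O)(O)O"))
  expect_identical(nrow(g), 2L)
  expect_identical(g$eq_type, c("acid", "acid"))
  expect_setequal(round(g$pka, 1), c(1.9, 6.7))
  expect_identical(anyDuplicated(g$atom), 0L)
})

test_that("the first matching rule claims the ionizable atom", {
  # a free amino acid's amine matches both the alpha-amine rule (first) and
  # the generic primary-amine rule (later): the alpha value must win
  g <- predict_pkas(mol_from_smiles("NCC(=O)O"))
  amine <- g[g$eq_type == "base", ]
  expect_identical(amine$label, "alpha_amine_primary")
  acid <- g[g$eq_type == "acid", ]
  expect_identical(acid$label, "alpha_carboxylic_acid")
  # explicit two-rule overlap through a custom table
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("name", "pattern", "c1_pos", "c1_pka", "c1_type",
                       "c2_pos", "c2_pka", "c2_type"), collapse = "\t"),
               "specific\t[OX2H1][CX3]=[OX1]\t1\t3.0\tacid\tNA\tNA\tNA",
               "generic\t[OX2H1]\t1\t5.0\tacid\tNA\tNA\tNA"), path)
  g2 <- predict_pkas(mol_from_smiles("CC(=O)O"), rules = pka_rules(path))
  expect_identical(nrow(g2), 1L)
  expect_equal(g2$pka, 3.0)
  # permuting rules that do not overlap leaves the result unchanged
  g3 <- predict_pkas(mol_from_smiles("NCCCCO"))
  expect_identical(g3$label, "primary_amine")
})

test_that("claimed atoms are never re-assigned across sources", {
  frag <- cleave_and_cap(mol_from_smiles("NCC(=O)O"))[[1]]
  g_all <- predict_pkas(frag)
  claimed <- g_all$atom
  g_after <- predict_pkas(frag, claimed = claimed)
  expect_identical(nrow(g_after), 0L)
})

test_that("out-of-window groups are dropped, not shifted", {
  # aliphatic alcohols (pKa ~ 14-16) have no rule at all
  expect_identical(nrow(predict_pkas(mol_from_smiles("CCO"))), 0L)
  # a custom rule outside the acid window is matched but not emitted
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("name", "pattern", "c1_pos", "c1_pka", "c1_type",
                       "c2_pos", "c2_pka", "c2_type"), collapse = "\t"),
               "alcohol\t[OX2H1][CX4]\t1\t14.2\tacid\tNA\tNA\tNA"), path)
  expect_identical(nrow(predict_pkas(mol_from_smiles("CCO"), rules = pka_rules(path))), 0L)
})

test_that("four-valent nitrogens are constantly ionized, amines are not", {
  expect_identical(nrow(find_constant_charges(mol_from_smiles("C[N+](C)(C)C"))), 1L)
  expect_identical(nrow(find_constant_charges(mol_from_smiles("CN(C)C"))), 0L)
  two <- find_constant_charges(mol_from_smiles("C[N+](C)(C)CCC[N+](C)(C)C"))
  expect_identical(sum(two$charge), 2L)
  # N-alkyl pyridinium counts; protonated amines do not (they are ionizable)
  expect_identical(nrow(find_constant_charges(mol_from_smiles("C[n+]1ccccc1"))), 1L)
  expect_identical(nrow(find_constant_charges(mol_from_smiles("CC[NH3+]"))), 0L)
})

test_that("a quaternized lysine feeds the permanent charge, not the pKa list", {
  m <- build_structure(peptide_spec("GKG", modifications = list(
    list(position = 2L, kind = "quaternize_lysine"))))
  res <- pi_consensus(m)
  expect_identical(res$q_constant, 1L)
  labs <- unlist(lapply(res$per_set$groups, function(g) g$label))
  expect_false(any(grepl("K sidechain", labs)))
  # the permanent charge shifts the whole curve up by one
  plain <- pi_consensus(build_structure("GGG"))
  expect_equal(res$per_set$q_at_ph - plain$per_set$q_at_ph,
               rep(1, 8), tolerance = 1e-6)
})
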