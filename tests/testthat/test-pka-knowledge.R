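test_that("the shipped tables return the published values verbatim", {
  tab <- published_pka_table()
  for (i in seq_len(nrow(tab))) {
    s <- get_pka_set(tab$set[i])
    expect_identical(s$nterm_default, tab$nterm[i], info = tab$set[i])
    expect_identical(s$cterm_default, tab$cterm[i], info = tab$set[i])
    for (r in c("C", "Y", "D", "E", "H", "K", "R")) {
      expect_identical(unname(s$sidechain[r]), tab[[r]][i],
                       info = paste(tab$set[i], r))
    }
  }
  g <- get_pka_set("Gauci")
  gt <- gauci_promost_sidechains()
  for (r in c("C", "Y", "D", "E", "H", "K", "R")) {
    expect_identical(unname(g$sidechain[r]), gt[[r]][1], info = paste("Gauci", r))
  }
})

test_that("per-residue and positional terminus values stay inside the published ranges", {
  g <- get_pka_set("Gauci")
  expect_true(all(c(g$nterm_default, g$nterm_by_residue) >= 6.50))
  expect_true(all(c(g$nterm_default, g$nterm_by_residue) <= 8.36))
  expect_true(all(c(g$cterm_default, g$cterm_by_residue) >= 3.55))
  expect_true(all(c(g$cterm_default, g$cterm_by_residue) <= 4.75))

  p <- get_pka_set("ProMoST")
  expect_true(all(c(p$nterm_default, p$nterm_by_residue) >= 6.67))
  expect_true(all(c(p$nterm_default, p$nterm_by_residue) <= 8.36))
  expect_true(all(c(p$cterm_default, p$cterm_by_residue) >= 3.17))
  expect_true(all(c(p$cterm_default, p$cterm_by_residue) <= 3.98))
  ranges <- list(C = c(8.00, 9.00), Y = c(9.34, 10.34), D = c(3.57, 4.57),
                 E = c(4.15, 4.75), H = c(4.89, 6.89), K = c(9.8, 10.30),
                 R = c(11.5, 12.5))
  for (r in names(ranges)) {
    v <- p$positional_sidechain[[r]]
    expect_true(all(v >= ranges[[r]][1] & v <= ranges[[r]][2]), info = r)
  }
})

test_that("every shipped pKa value lies in [0, 14] and sets are well-formed", {
  for (nm in list_pka_sets()) {
    s <- get_pka_set(nm)
    vals <- c(s$nterm_default, s$cterm_default, s$nterm_by_residue,
              s$cterm_by_residue, s$sidechain, unlist(s$positional_sidechain))
    expect_true(all(vals >= 0 & vals <= 14), info = nm)
    expect_setequal(names(s$sidechain)[names(s$sidechain) != ""],
                    intersect(names(s$sidechain), c("C", "Y", "D", "E", "H", "K", "R")))
  }
})

test_that("set listing is deterministic and complete; unknown names error helpfully", {
  nm <- list_pka_sets()
  expect_length(nm, 8L)
  expect_true("Gauci" %in% nm)
  expect_identical(nm, list_pka_sets())
  expect_identical(get_pka_set("Lehninger"), get_pka_set("Lehninger"))
  expect_error(get_pka_set("nosuchset"), "unknown pKa set")
  expect_error(get_pka_set("nosuchset"), "Gauci") # message lists valid names
})

test_that("the admissibility window follows the below-12 / above-2 convention", {
  expect_false(admissible(13.5, "acid"))
  expect_false(admissible(12, "acid"))   # strict at the primary acid bound
  expect_true(admissible(11.999, "acid"))
  expect_false(admissible(1.0, "base"))
  expect_false(admissible(2, "base"))    # strict at the primary base bound
  expect_true(admissible(2.001, "base"))
  expect_false(admissible(-6.0, "acid"))
  expect_true(admissible(-5, "acid"))    # inclusive outer guard
  expect_true(admissible(15, "base"))
  expect_false(admissible(15.1, "base"))
  expect_true(admissible(4.25, "acid"))
})

test_that("admissibility is monotone towards the window centre", {
  w <- pka_window()
  centre_a <- (w$acid_lower + w$acid_upper) / 2
  for (pk in seq(-8, 16, by = 0.5)) {
    if (admissible(pk, "acid", w)) {
      closer <- (pk + centre_a) / 2
      expect_true(admissible(closer, "acid", w), info = pk)
    }
  }
})

test_that("user pKa-set files load through the documented format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("set\tparameter\tresidue\tposition\tpka",
               "Custom\tnterm\t*\tany\t9.0",
               "Custom\tcterm\t*\tany\t2.0",
               sprintf("Custom\tsidechain\t%s\tany\t%s",
                       c("C", "Y", "D", "E", "H", "K", "R"),
                       c(9, 10, 4, 4.4, 6, 10.4, 12))), path)
  sets <- read_pka_sets(path)
  expect_named(sets, "Custom")
  res <- sequence_consensus("GG", sets = sets)
  expect_equal(res$pi_mean, (9.0 + 2.0) / 2, tolerance = 1e-4)
})
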