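grp <- function(pkas, types) {
  tibble::tibble(pka = pkas, eq_type = types, source = "test",
                 label = types, atom = NA_integer_)
}

test_that("net charge follows the closed-form independent-site model", {
  expect_equal(net_charge(c(0, 7, 14), grp(numeric(0), character(0)), q_constant = 1),
               c(1, 1, 1))
  expect_equal(net_charge(9, grp(9, "base")), 0.5)
  expect_equal(net_charge(7.4, grp(4.317, "acid")),
               -1 / (1 + 10^(4.317 - 7.4)))
  # additivity of two groups
  g2 <- grp(c(4, 9), c("acid", "base"))
  expect_equal(net_charge(5, g2),
               net_charge(5, grp(4, "acid")) + net_charge(5, grp(9, "base")))
})

test_that("charge curves are non-increasing in pH with the correct limits", {
  set.seed(11)
  for (k in 1:25) {
    g <- random_groups(sample(0:3, 1), sample(0:3, 1))
    qc <- sample(-1:1, 1)
    cc <- charge_curve(g$tbl, q_constant = qc)
    expect_true(all(diff(cc$q) <= 1e-12), info = k)
    # dual-route check of the charge model itself
    expect_equal(cc$q, oracle_charge(cc$ph, g$acids, g$bases, qc), tolerance = 1e-12)
    # limits: with every pKa well inside [0, 14], bases are ~fully protonated
    # at pH 0 and acids ~fully ionized at pH 14
    if (all(g$acids > 2)) expect_lt(abs(cc$q[1] - (length(g$bases) + qc)), 0.05)
    if (all(g$bases < 12)) expect_lt(abs(cc$q[nrow(cc)] - (qc - length(g$acids))), 0.05)
  }
})

test_that("the bisection solver reproduces simple closed-form isoelectric points", {
  s <- solve_pi(grp(c(4, 9), c("acid", "base")))
  expect_equal(s$pi, 6.5, tolerance = 1e-4)
  expect_identical(s$status, "defined")
  # glycine under Lehninger: midpoint of 2.34 and 9.69
  g <- groups_from_sequence("G", get_pka_set("Lehninger"))
  expect_equal(solve_pi(g)$pi, (2.34 + 9.69) / 2, tolerance = 1e-3)
  # bit-identical determinism
  expect_identical(solve_pi(grp(c(3.3, 8.1), c("acid", "base")))$pi,
                   solve_pi(grp(c(3.3, 8.1), c("acid", "base")))$pi)
})

test_that("curves that never cross zero are classified, not silently rooted", {
  only_base <- solve_pi(grp(10, "base"))
  expect_identical(only_base$status, "asymptotic_touch") # Q -> 0+ at high pH
  expect_true(only_base$pi > 11)
  strong_bases <- solve_pi(grp(c(12, 13), c("base", "base")))
  expect_identical(strong_bases$status, "no_crossing")
  expect_true(is.na(strong_bases$pi))
  const <- solve_pi(grp(numeric(0), character(0)), q_constant = 2)
  expect_identical(const$status, "no_crossing")
})

test_that("every defined pI satisfies the 0.01 e charge tolerance and matches a dense-grid oracle", {
  set.seed(202)
  n_checked <- 0L
  for (k in 1:200) {
    g <- random_groups(sample(1:4, 1), sample(1:4, 1))
    s <- solve_pi(g$tbl)
    root <- oracle_root(g$acids, g$bases)
    if (s$status == "defined") {
      expect_lte(abs(net_charge(s$pi, g$tbl)), 0.01)
      expect_false(is.na(root), info = k)
      expect_lt(abs(s$pi - root), 0.01)
      n_checked <- n_checked + 1L
    } else {
      expect_true(is.na(root), info = k)
    }
  }
  expect_gte(n_checked, 150L)
})

test_that("the isoelectric interval brackets the |Q| <= 0.05 band", {
  g <- grp(c(4, 9), c("acid", "base"))
  ival <- isoelectric_interval(g)
  # independently located band edges (dense grid): ~ (5.28, 7.72)
  oracle <- oracle_interval(4, 9)
  expect_equal(unname(ival), oracle, tolerance = 1e-3)
  expect_equal(unname(ival), c(5.28, 7.72), tolerance = 0.01)
  expect_equal(mean(ival), 6.5, tolerance = 1e-3) # symmetric about the pI
  # only-base case: the high-pH tail is inside the band
  tail_only <- isoelectric_interval(grp(8, "base"))
  expect_equal(unname(tail_only[2]), 14)
  expect_true(tail_only[1] > 9)
  # a permanent +2 never becomes uncharged
  expect_null(isoelectric_interval(grp(numeric(0), character(0)), q_constant = 2))
})

test_that("random interval edges agree with the dense-grid oracle", {
  set.seed(303)
  for (k in 1:40) {
    g <- random_groups(sample(1:3, 1), sample(1:3, 1))
    ival <- isoelectric_interval(g$tbl)
    oracle <- oracle_interval(g$acids, g$bases)
    if (is.null(oracle)) {
      expect_null(ival, info = k)
    } else {
      expect_equal(unname(ival), oracle, tolerance = 1e-3, info = k)
    }
  }
})
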