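# Shared fixtures and independent oracles for the test suite.

# Vectorized closed-form net charge, written independently of the package's
# net_charge() so solver tests have a genuine second route.
oracle_charge <- function(ph, acids, bases, qc = 0) {
  q <- rep(qc, length(ph))
  for (pk in bases) q <- q + 1 / (1 + 10^(ph - pk))
  for (pk in acids) q <- q - 1 / (1 + 10^(pk - ph))
  q
}

# Dense-grid root locator: first sign change of Q on a 1e-4 grid.
oracle_root <- function(acids, bases, qc = 0, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- oracle_charge(grid, acids, bases, qc)
  s <- sign(q)
  idx <- which(s[-1] != s[-length(s)] & s[-length(s)] != 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  # linear interpolation inside the bracketing step
  grid[i] + step * q[i] / (q[i] - q[i + 1])
}

# Dense-grid isoelectric interval: extreme grid points with |Q| <= band.
oracle_interval <- function(acids, bases, qc = 0, band = 0.05, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- oracle_charge(grid, acids, bases, qc)
  inside <- which(abs(q) <= band)
  if (!length(inside)) return(NULL)
  c(grid[min(inside)], grid[max(inside)])
}

# Random ionizable-group tables drawn inside the admissibility windows.
random_groups <- function(n_acids, n_bases, rng) {
  acids <- stats::runif(n_acids, -2, 11)
  bases <- stats::runif(n_bases, 3, 13)
  list(
    acids = acids, bases = bases,
    tbl = dplyr::bind_rows(
      tibble::tibble(pka = acids, eq_type = "acid", source = "test",
                     label = "acid", atom = NA_integer_),
      tibble::tibble(pka = bases, eq_type = "base", source = "test",
                     label = "base", atom = NA_integer_)
    )
  )
}

# A capped single-residue fragment: the middle piece of a G-X-G tripeptide.
capped_fragment <- function(residue) {
  m <- build_structure(paste0("G", residue, "G"))
  frags <- cleave_and_cap(m)
  stopifnot(length(frags) == 3L)
  frags[[2]]
}

# Functional-group panel for the rule engine: SMILES plus the expected
# emitted (acid, base) group counts.
rule_panel <- function() {
  tibble::tribble(
    ~name,                ~smiles,                         ~acids, ~bases,
    "acetic acid",        "CC(=O)O",                        1L, 0L,
    "glycine (free)",     "NCC(=O)O",                       1L, 1L,
    "phenol",             "Oc1ccccc1",                      1L, 0L,
    "p-cresol",           "Cc1ccc(O)cc1",                   1L, 0L,
    "ethanol",            "CCO",                            0L, 0L,
    "ethanethiol",        "CCS",                            1L, 0L,
    "thiophenol",         "Sc1ccccc1",                      1L, 0L,
    "methyl sulfate",     "COS(=O)(=O)O",                   1L, 0L,
    "methanesulfonic",    "CS(=O)(=O)O",                    1L, 0L,
    "methyl phosphate",   "COP(=O)(O)O",                    2L, 0L,
    "dimethyl phosphate", "COP(=O)(OC)O",                   1L, 0L,
    "methylphosphonic",   "CP(=O)(O)O",                     2L, 0L,
    "phenyltetrazole",    "c1ccc(cc1)c1nnn[nH]1",           1L, 0L,
    "imidazole",          "c1c[nH]cn1",                     0L, 1L,
    "pyridine",           "c1ccncc1",                       0L, 1L,
    "aniline",            "Nc1ccccc1",                      0L, 1L,
    "N-methylaniline",    "CNc1ccccc1",                     0L, 1L,
    "benzylamine",        "NCc1ccccc1",                     0L, 1L,
    "dimethylamine",      "CNC",                            0L, 1L,
    "trimethylamine",     "CN(C)C",                         0L, 1L,
    "guanidine",          "NC(=N)N",                        0L, 1L,
    "acetamidine",        "CC(=N)N",                        0L, 1L,
    "acetamide",          "CC(=O)N",                        0L, 0L,
    "N-methylacetamide",  "CC(=O)NC",                       0L, 0L,
    "succinimide",        "O=C1CCC(=O)N1",                  1L, 0L,
    "methanesulfonamide", "CS(=O)(=O)N",                    1L, 0L,
    "acetohydroxamic",    "CC(=O)NO",                       1L, 0L,
    "indole",             "c1ccc2[nH]ccc2c1",               0L, 0L,
    "hexane",             "CCCCCC",                         0L, 0L,
    "tetramethylammonium","C[N+](C)(C)C",                   0L, 0L
  )
}

# The published canonical pKa table, frozen for fidelity tests:
# N-term, C-term, then side chains C Y D E H K R.
published_pka_table <- function() {
  tibble::tribble(
    ~set,           ~nterm, ~cterm,   ~C,     ~Y,    ~D,    ~E,    ~H,     ~K,     ~R,
    "IPC_peptide",   9.564,  2.383,  8.297, 10.071, 3.887, 4.317, 6.018, 10.517, 12.503,
    "IPC2_peptide",  7.947,  2.977,  9.439,  9.153, 3.969, 4.507, 6.439,  8.165, 11.493,
    "Grimsley",      7.7,    3.3,    6.8,   10.3,   3.5,   4.2,   6.6,   10.5,   12.04,
    "Toseland",      8.71,   3.19,   6.87,   9.61,  3.6,   4.29,  6.33,  10.45,  12.0,
    "Thurlkill",     8.0,    3.67,   8.55,   9.84,  3.67,  4.25,  6.54,  10.4,   12.0,
    "Lehninger",     9.69,   2.34,   8.33,  10.0,   3.86,  4.25,  6.0,   10.5,   12.4
  )
}

gauci_promost_sidechains <- function() {
  tibble::tribble(
    ~set,      ~C,   ~Y,    ~D,    ~E,    ~H,    ~K,    ~R,
    "Gauci",    9.0, 10.0,  4.05,  4.45,  5.98, 10.0,  12.0
  )
}
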