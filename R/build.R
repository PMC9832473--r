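# Programmatic peptide construction: canonical structures are assembled from
# templated monomer graphs joined through amide bonds (no SMILES string
# concatenation), so every test structure carries exact atom bookkeeping.
# Modification operators mirror the noncanonical features of the validation
# chemistry: N-methylation, beta-homologation, lysine quaternization,
# disulfide bridges, N-terminal acetylation/pyroglutamate and C-terminal
# carboxamide.

# Side chains as local graphs: atoms (elements), bonds (local indices,
# order), attachment of local atom 1 to the alpha carbon. Proline's chain
# closes back onto the backbone nitrogen (ring_to_n). Histidine is built in
# the N-epsilon-H tautomer; arginine in the neutral guanidine form.
.SIDE_CHAINS <- list(
  G = NULL,
  A = list(el = "C", bonds = NULL),
  V = list(el = c("C", "C", "C"), bonds = rbind(c(1, 2, 1), c(1, 3, 1))),
  L = list(el = c("C", "C", "C", "C"), bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(2, 4, 1))),
  I = list(el = c("C", "C", "C", "C"), bonds = rbind(c(1, 2, 1), c(1, 3, 1), c(3, 4, 1))),
  M = list(el = c("C", "C", "S", "C"), bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
  F = list(el = c("C", "C", "C", "C", "C", "C", "C"),
           bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1), c(4, 5, 2), c(5, 6, 1), c(6, 7, 2), c(7, 2, 1))),
  W = list(el = c("C", "C", "C", "N", "C", "C", "C", "C", "C", "C"),
           bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1), c(4, 5, 1), c(5, 6, 2),
                         c(6, 7, 1), c(7, 8, 2), c(8, 9, 1), c(9, 10, 2), c(10, 2, 1), c(10, 5, 1))),
  S = list(el = c("C", "O"), bonds = rbind(c(1, 2, 1))),
  T = list(el = c("C", "O", "C"), bonds = rbind(c(1, 2, 1), c(1, 3, 1))),
  C = list(el = c("C", "S"), bonds = rbind(c(1, 2, 1))),
  Y = list(el = c("C", "C", "C", "C", "C", "O", "C", "C"),
           bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1), c(4, 5, 2), c(5, 6, 1),
                         c(5, 7, 1), c(7, 8, 2), c(8, 2, 1))),
  N = list(el = c("C", "C", "O", "N"), bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1))),
  Q = list(el = c("C", "C", "C", "O", "N"),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 2), c(3, 5, 1))),
  D = list(el = c("C", "C", "O", "O"), bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1))),
  E = list(el = c("C", "C", "C", "O", "O"),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 2), c(3, 5, 1))),
  K = list(el = c("C", "C", "C", "C", "N"),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1))),
  R = list(el = c("C", "C", "C", "N", "C", "N", "N"),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1), c(5, 6, 2), c(5, 7, 1))),
  H = list(el = c("C", "C", "N", "C", "N", "C"),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 2), c(4, 5, 1), c(5, 6, 1), c(6, 2, 2))),
  P = list(el = c("C", "C", "C"), bonds = rbind(c(1, 2, 1), c(2, 3, 1)), ring_to_n = 3L)
)

.MOD_KINDS <- c("n_methyl", "beta_homo", "quaternize_lysine", "disulfide_pair")

#' Specify a test peptide
#'
#' @param sequence One-letter sequence (canonical residues only).
#' @param cterm `"acid"` (free carboxylic acid) or `"primary_amide"`.
#' @param nterm `"free"`, `"acetylated"` or `"pyroglutamate"` (first residue
#'   must then be Q or E).
#' @param modifications A list of `list(position =, kind =)` entries with
#'   kind one of `n_methyl`, `beta_homo`, `quaternize_lysine` (residue must
#'   be K) or `disulfide_pair` (position = a vector of two Cys positions).
#' @return A validated `peptide_spec` object.
#' @export
peptide_spec <- function(sequence, cterm = c("acid", "primary_amide"),
                         nterm = c("free", "acetylated", "pyroglutamate"),
                         modifications = list()) {
  cterm <- match.arg(cterm)
  nterm <- match.arg(nterm)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!length(chars)) abort("empty peptide sequence")
  bad <- which(!chars %in% .AA_LETTERS)
  if (length(bad)) abort(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]))
  if (nterm == "pyroglutamate" && !chars[1] %in% c("Q", "E")) {
    abort("pyroglutamate N-terminus requires Q or E as the first residue")
  }
  for (mod in modifications) {
    if (!is.list(mod) || is.null(mod$kind) || is.null(mod$position)) {
      abort("each modification needs 'position' and 'kind'")
    }
    if (!mod$kind %in% .MOD_KINDS) abort(sprintf("unknown modification kind '%s'", mod$kind))
    if (mod$kind == "disulfide_pair") {
      if (length(mod$position) != 2L || !all(chars[mod$position] == "C")) {
        abort("disulfide_pair needs two Cys positions")
      }
    } else {
      if (length(mod$position) != 1L || mod$position < 1L || mod$position > length(chars)) {
        abort(sprintf("modification position %s out of range", toString(mod$position)))
      }
      if (mod$kind == "quaternize_lysine" && chars[mod$position] != "K") {
        abort("quaternize_lysine requires a K residue")
      }
      if (mod$kind == "n_methyl" && chars[mod$position] == "P") {
        abort("cannot N-methylate proline (tertiary backbone nitrogen)")
      }
    }
  }
  structure(list(sequence = paste(chars, collapse = ""), residues = chars,
                 cterm = cterm, nterm = nterm, modifications = modifications),
            class = "peptide_spec")
}

#' Build the chemical structure of a peptide specification
#'
#' Assembles the molecular graph monomer by monomer; with no modifications,
#' a free N-terminus and an acid C-terminus the result is the canonical
#' linear peptide.
#'
#' @param spec A [peptide_spec()] (or a plain sequence string, taken with
#'   default termini).
#' @return A `pep_mol`.
#' @export
build_structure <- function(spec) {
  if (is.character(spec)) spec <- peptide_spec(spec)
  stopifnot(inherits(spec, "peptide_spec"))
  chars <- spec$residues
  nres <- length(chars)
  beta_pos <- vapply(spec$modifications, function(m) if (m$kind == "beta_homo") m$position else NA_integer_, numeric(1))
  elements <- character(0); charges <- integer(0)
  bonds <- list()
  add_atom <- function(el, charge = 0L) {
    elements[length(elements) + 1L] <<- el
    charges[length(charges) + 1L] <<- charge
    length(elements)
  }
  add_bond <- function(a, b, order = 1L) {
    bonds[[length(bonds) + 1L]] <<- c(a, b, order)
  }
  N_idx <- integer(nres); CA_idx <- integer(nres); C_idx <- integer(nres)
  side_idx <- vector("list", nres)
  prev_C <- NA_integer_
  for (i in seq_len(nres)) {
    N <- add_atom("N"); CA <- add_atom("C")
    add_bond(N, CA)
    carbonyl_from <- CA
    if (i %in% beta_pos) { # beta-homo residue: extra CH2 before the carbonyl
      CB2 <- add_atom("C"); add_bond(CA, CB2); carbonyl_from <- CB2
    }
    Cc <- add_atom("C"); O <- add_atom("O")
    add_bond(carbonyl_from, Cc); add_bond(Cc, O, 2L)
    sc <- .SIDE_CHAINS[[chars[i]]]
    if (!is.null(sc)) {
      base <- length(elements)
      for (el in sc$el) add_atom(el)
      if (!is.null(sc$bonds)) {
        for (k in seq_len(nrow(sc$bonds))) add_bond(base + sc$bonds[k, 1], base + sc$bonds[k, 2], sc$bonds[k, 3])
      }
      add_bond(CA, base + 1L)
      if (!is.null(sc$ring_to_n)) add_bond(base + sc$ring_to_n, N)
      side_idx[[i]] <- base + seq_along(sc$el)
    }
    if (!is.na(prev_C)) add_bond(prev_C, N)
    N_idx[i] <- N; CA_idx[i] <- CA; C_idx[i] <- Cc
    prev_C <- Cc
  }
  # C-terminus
  if (spec$cterm == "acid") {
    OXT <- add_atom("O"); add_bond(C_idx[nres], OXT)
  } else {
    NT <- add_atom("N"); add_bond(C_idx[nres], NT)
  }
  # N-terminus
  if (spec$nterm == "acetylated") {
    Cac <- add_atom("C"); Oac <- add_atom("O"); Cme <- add_atom("C")
    add_bond(N_idx[1], Cac); add_bond(Cac, Oac, 2L); add_bond(Cac, Cme)
  } else if (spec$nterm == "pyroglutamate") {
    # cyclize the Glu/Gln side-chain carbonyl onto the backbone nitrogen,
    # dropping the distal OE2/NE2 atom (5-membered lactam)
    sc <- side_idx[[1]]
    add_bond(sc[3], N_idx[1])
    drop_atom <- sc[5]
  }
  for (mod in spec$modifications) {
    if (mod$kind == "n_methyl") {
      add_bond(N_idx[mod$position], add_atom("C"))
    } else if (mod$kind == "quaternize_lysine") {
      NZ <- side_idx[[mod$position]][5]
      for (k in 1:3) add_bond(NZ, add_atom("C"))
      charges[NZ] <- 1L
    } else if (mod$kind == "disulfide_pair") {
      s1 <- side_idx[[mod$position[1]]][2]
      s2 <- side_idx[[mod$position[2]]][2]
      add_bond(s1, s2)
    }
  }
  bond_tbl <- tibble(
    a1 = vapply(bonds, `[`, numeric(1), 1),
    a2 = vapply(bonds, `[`, numeric(1), 2),
    order = vapply(bonds, `[`, numeric(1), 3)
  )
  m <- mol_graph(elements, bond_tbl, charges = charges)
  if (spec$nterm == "pyroglutamate") m <- .mol_edit(m, drop_atoms = drop_atom)
  m$atoms$orig <- seq_len(nrow(m$atoms))
  m
}

#' Draw a random all-canonical peptide specification
#'
#' Reproducible for a fixed seed; residues are uniform over the 20 canonical
#' letters. The caller's random-number state is left untouched.
#'
#' @param length Number of residues (>= 1).
#' @param seed Integer seed.
#' @return A `peptide_spec`.
#' @export
random_canonical_spec <- function(length, seed) {
  stopifnot(length >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  peptide_spec(paste(sample(.AA_LETTERS, length, replace = TRUE), collapse = ""))
}
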