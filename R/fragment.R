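# Backbone fragmentation: cleave every secondary and tertiary amide bond and
# cap the cut ends — acetyl on the freed nitrogen, methyl on the freed
# carbonyl carbon (methyl ketone) — so each fragment keeps the
# electron-withdrawing environment of the peptide backbone.

# A cleavable bond is the C(=O)-N single bond of a secondary/tertiary amide:
# the carbonyl carbon's remaining substituent must be carbon (excludes ureas,
# carbamates, formamides) and the nitrogen must carry at least one carbon
# besides the acyl group (excludes primary amides such as Asn/Gln side chains
# and C-terminal carboxamides). Amides inside small rings (lactams, ring size
# <= 7, e.g. pyroglutamate) are kept intact; amides in macrocycles are
# cleaved. Bonds involving cap atoms from a previous fragmentation round are
# never cleaved, which makes the operation idempotent on its own output.
.AMIDE_PATTERN <- "[CX3](=[OX1])([#6])[NX3]([#6])"

.find_cleavable_amides <- function(m) {
  hits <- match_pattern(m, .AMIDE_PATTERN)
  out <- list()
  seen <- character(0)
  for (h in hits) {
    cc <- h[1]; nn <- h[4]
    key <- paste(cc, nn)
    if (key %in% seen) next
    seen <- c(seen, key)
    if (m$atoms$is_cap[cc] || m$atoms$is_cap[nn]) next
    k <- .bond_between(m, cc, nn)[1]
    if (m$bonds$in_ring[k]) {
      sizes <- vapply(m$rings, function(r) if (cc %in% r && nn %in% r) length(r) else NA_integer_, integer(1))
      sizes <- sizes[!is.na(sizes)]
      if (length(sizes) && min(sizes) <= 7L) next
    }
    out[[length(out) + 1L]] <- list(bond = k, c_atom = cc, n_atom = nn)
  }
  out
}

#' Cleave all backbone amide bonds and cap the fragments
#'
#' Implements the fragmentation step of the structure-based pI workflow:
#' every secondary and tertiary amide bond is cut, freed amines receive an
#' acetyl cap and freed carbonyl carbons a methyl cap (methyl ketone), and
#' the connected components are returned as fragments that remember which
#' atom of the input molecule each non-cap atom came from.
#'
#' @param m A `pep_mol` (or a fragment from a previous call, which is
#'   returned unchanged apart from list wrapping).
#' @return A list of `pep_fragment` objects (each also a `pep_mol`), ordered
#'   by their first original atom. Attributes `n_cut_n_side` and
#'   `n_cut_c_side` count the cuts at which the fragment kept the nitrogen
#'   and the carbonyl, respectively.
#' @export
cleave_and_cap <- function(m) {
  stopifnot(inherits(m, "pep_mol"))
  cuts <- .find_cleavable_amides(m)
  if (!length(cuts)) {
    f <- m
    attr(f, "n_cut_n_side") <- 0L
    attr(f, "n_cut_c_side") <- 0L
    class(f) <- c("pep_fragment", "pep_mol")
    return(list(f))
  }
  n0 <- nrow(m$atoms)
  add_atoms <- list()
  add_bonds <- list()
  next_idx <- n0
  for (cut in cuts) {
    # acetyl on the nitrogen: N-C(=O)-CH3
    cacyl <- next_idx + 1L; oacyl <- next_idx + 2L; cme <- next_idx + 3L
    # methyl on the carbonyl carbon
    cket <- next_idx + 4L
    next_idx <- next_idx + 4L
    add_atoms[[length(add_atoms) + 1L]] <- tibble(
      element = c("C", "O", "C", "C"), charge = 0L, is_cap = TRUE, orig = NA_integer_
    )
    add_bonds[[length(add_bonds) + 1L]] <- tibble(
      a1 = c(cut$n_atom, cacyl, cacyl, cut$c_atom),
      a2 = c(cacyl, oacyl, cme, cket),
      order = c(1L, 2L, 1L, 1L)
    )
  }
  cut_info <- tibble(
    n_atom = vapply(cuts, `[[`, integer(1), "n_atom"),
    c_atom = vapply(cuts, `[[`, integer(1), "c_atom")
  )
  edited <- .mol_edit(m,
    drop_bonds = vapply(cuts, `[[`, integer(1), "bond"),
    add_atoms = dplyr::bind_rows(add_atoms),
    add_bonds = dplyr::bind_rows(add_bonds)
  )
  comps <- .mol_components(edited)
  frags <- lapply(comps, function(idx) {
    f <- .mol_subset(edited, idx)
    attr(f, "n_cut_n_side") <- sum(cut_info$n_atom %in% idx)
    attr(f, "n_cut_c_side") <- sum(cut_info$c_atom %in% idx)
    class(f) <- c("pep_fragment", "pep_mol")
    f
  })
  first_orig <- vapply(frags, function(f) {
    o <- f$atoms$orig[!is.na(f$atoms$orig)]
    if (length(o)) min(o) else .Machine$integer.max
  }, numeric(1))
  unname(frags[order(first_orig)])
}

#' @export
print.pep_fragment <- function(x, ...) {
  cat(sprintf("<pep_fragment> %s; cuts: %d N-side, %d C-side, %d cap atoms\n",
              mol_formula(x), attr(x, "n_cut_n_side"), attr(x, "n_cut_c_side"),
              sum(x$atoms$is_cap)))
  invisible(x)
}
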