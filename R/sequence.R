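# Sequence-based pI calculation: the same charge model and consensus
# machinery as the structure pipeline, but ionizable groups are read off the
# one-letter sequence. Both termini are assumed ionizable; the side chains of
# noncanonical residues, written X, contribute nothing.

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate and canonicalize a one-letter peptide sequence
#'
#' @param sequence A character scalar over the 20 canonical letters plus `X`
#'   (case-insensitive; canonicalized to upper case).
#' @return The validated upper-case sequence.
#' @export
parse_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(trimws(sequence))
  if (!nzchar(s)) abort("empty sequence")
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c(.AA_LETTERS, "X"))
  if (length(bad)) {
    abort(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]))
  }
  s
}

#' Ionizable groups of a one-letter sequence
#'
#' One basic group for the N-terminus, one acidic group for the C-terminus
#' (per-residue values when the set provides them) and one group per
#' ionizable side chain among C, Y, D, E, H, K, R. Position-dependent sets
#' consult whether the residue sits at the N-terminus, C-terminus or inside
#' the chain. `X` contributes no side-chain group; its termini use the set
#' defaults.
#'
#' @param sequence One-letter sequence (validated by [parse_sequence()]).
#' @param set A `pka_set`.
#' @return A tibble of ionizable groups; `atom` is the residue position.
#' @export
groups_from_sequence <- function(sequence, set) {
  stopifnot(inherits(set, "pka_set"))
  s <- parse_sequence(sequence)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  out <- list(
    .ionizable_group(.terminus_pka(set, "nterm", chars[1]), "base",
                     "canonical_set", sprintf("N-terminus (%s)", chars[1]), 1L),
    .ionizable_group(.terminus_pka(set, "cterm", chars[n]), "acid",
                     "canonical_set", sprintf("C-terminus (%s)", chars[n]), n)
  )
  for (i in seq_len(n)) {
    r <- chars[i]
    if (!r %in% .IONIZABLE_RESIDUES) next
    pos_class <- if (i == 1L) "n_terminal" else if (i == n) "c_terminal" else "internal"
    out[[length(out) + 1L]] <- .ionizable_group(
      .sidechain_pka(set, r, pos_class), .residue_eq_type(r),
      "canonical_set", sprintf("%s sidechain", r), i
    )
  }
  dplyr::bind_rows(out)
}

#' Consensus isoelectric point of a one-letter sequence
#'
#' Mechanically identical to [pi_consensus()] but with groups derived from
#' the sequence; reported as mean pI (and SD) over the same pKa sets.
#'
#' @param sequence One-letter sequence (20 canonical letters plus `X`).
#' @inheritParams pi_consensus
#' @return A `pi_result` object.
#' @export
sequence_consensus <- function(sequence, sets = NULL, ph_charge = 7.4) {
  s <- parse_sequence(sequence)
  sets <- .resolve_sets(sets)
  groups_by_set <- lapply(sets, function(st) groups_from_sequence(s, st))
  .aggregate_pi(groups_by_set, 0L, s, "sequence", ph_charge)
}
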