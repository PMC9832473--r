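# Canonical-residue recognition: a capped fragment is accepted as a canonical
# amino acid when one residue template covers every heavy atom apart from the
# caps and the single C-terminal substituent (OH of a free acid, or NH2 of a
# primary carboxamide). Individual amino acids with both termini free are not
# recognized here; the paper's workflow routes them to the rule-based
# predictor.

.canonical_templates <- function() {
  if (is.null(.pkg_cache$templates)) {
    path <- system.file("extdata", "canonical_templates.tsv", package = "pepiso", mustWork = TRUE)
    tab <- .read_table_file(path)
    tab$compiled <- lapply(tab$pattern, compile_pattern)
    .pkg_cache$templates <- tab
  }
  .pkg_cache$templates
}

.empty_matches <- function() {
  tibble(residue = character(), kind = character(), position_class = character(),
         atom_frag = integer(), atom = integer())
}

#' Match a capped fragment against the canonical residue templates
#'
#' @param fragment A `pep_fragment` from [cleave_and_cap()] (a plain
#'   `pep_mol` is accepted and treated as an uncut fragment).
#' @return A tibble of matches with columns `residue` (one-letter code),
#'   `kind` (`sidechain`, `nterm_amine`, `cterm_acid`,
#'   `cterm_primary_amide`), `position_class` (`n_terminal`, `internal`,
#'   `c_terminal`), `atom_frag` (ionizable atom index in the fragment, `NA`
#'   for non-ionizable matches) and `atom` (the corresponding atom of the
#'   original molecule). Zero rows when the fragment is not a canonical
#'   residue (including the lone-amino-acid case).
#' @export
match_canonical <- function(fragment) {
  stopifnot(inherits(fragment, "pep_mol"))
  m <- mol_neutralize(fragment)
  templates <- .canonical_templates()
  allatoms <- seq_len(nrow(m$atoms))
  adj <- .mol_neighbors(m)
  for (i in seq_len(nrow(templates))) {
    hits <- match_pattern(m, templates$compiled[[i]], unique_sets = TRUE)
    for (map in hits) {
      res <- .validate_residue_match(m, adj, map, templates[i, ], allatoms, fragment)
      if (!is.null(res)) return(res)
    }
  }
  .empty_matches()
}

# An acetyl group attached at `c_atom` (the carbonyl carbon of a cap):
# returns the covered atom set {C, =O, CH3}, or NULL if the shape is wrong.
# Caps are recognized structurally so that fragments parsed from files match
# exactly like fragments produced by cleave_and_cap.
.acetyl_cover <- function(m, adj, c_atom, from_n) {
  if (m$atoms$element[c_atom] != "C") return(NULL)
  nb <- setdiff(adj[[c_atom]], from_n)
  if (length(nb) != 2L) return(NULL)
  o <- nb[m$atoms$element[nb] == "O" & m$atoms$nH[nb] == 0L]
  me <- nb[m$atoms$element[nb] == "C" & m$atoms$nH[nb] == 3L]
  if (length(o) != 1L || length(me) != 1L) return(NULL)
  if (!length(.bond_between(m, c_atom, o)) || m$bonds$order[.bond_between(m, c_atom, o)] != 2L) return(NULL)
  c(c_atom, o, me)
}

.validate_residue_match <- function(m, adj, map, tmpl, allatoms, fragment) {
  n_atom <- map[1]
  c_atom <- map[tmpl$c_pos]
  matched <- map
  others <- setdiff(allatoms, matched)
  cap_cover <- which(m$atoms$is_cap)
  # nitrogen state: free amine, or capped by a (structural or flagged) acetyl
  n_unmatched <- setdiff(adj[[n_atom]], matched)
  n_state <- NULL
  if (length(n_unmatched) == 0L) n_state <- "free"
  else if (length(n_unmatched) == 1L) {
    acov <- .acetyl_cover(m, adj, n_unmatched, n_atom)
    if (m$atoms$is_cap[n_unmatched] || !is.null(acov)) {
      n_state <- "capped"
      if (!is.null(acov)) cap_cover <- union(cap_cover, acov)
    }
  }
  if (is.null(n_state)) return(NULL)
  # carbonyl state: exactly one substituent besides the matched CA and =O
  c_unmatched <- setdiff(adj[[c_atom]], matched)
  if (length(c_unmatched) != 1L) return(NULL)
  t_atom <- c_unmatched
  c_state <- if (m$atoms$is_cap[t_atom] ||
                 (m$atoms$element[t_atom] == "C" && m$atoms$nH[t_atom] == 3L &&
                  length(adj[[t_atom]]) == 1L)) "capped"
             else if (m$atoms$element[t_atom] == "O" && m$atoms$nH[t_atom] == 1L &&
                      m$atoms$charge[t_atom] == 0L && length(adj[[t_atom]]) == 1L) "acid"
             else if (m$atoms$element[t_atom] == "N" && m$atoms$nH[t_atom] == 2L &&
                      m$atoms$charge[t_atom] == 0L && length(adj[[t_atom]]) == 1L) "amide"
             else return(NULL)
  if (c_state == "capped") cap_cover <- union(cap_cover, t_atom)
  # full coverage: everything else must belong to a cap
  if (!all(others %in% c(cap_cover, t_atom))) return(NULL)
  if (n_state == "free" && c_state != "capped") return(NULL) # lone amino acid
  position_class <- if (n_state == "free") "n_terminal"
                    else if (c_state == "capped") "internal"
                    else "c_terminal"
  orig <- fragment$atoms$orig
  rows <- list(tibble(
    residue = tmpl$residue, kind = "sidechain", position_class = position_class,
    atom_frag = if (tmpl$ion_pos > 0L) map[tmpl$ion_pos] else NA_integer_,
    atom = if (tmpl$ion_pos > 0L) orig[map[tmpl$ion_pos]] else NA_integer_
  ))
  if (n_state == "free") {
    rows[[length(rows) + 1L]] <- tibble(
      residue = tmpl$residue, kind = "nterm_amine", position_class = position_class,
      atom_frag = n_atom, atom = orig[n_atom]
    )
  }
  if (c_state == "acid") {
    rows[[length(rows) + 1L]] <- tibble(
      residue = tmpl$residue, kind = "cterm_acid", position_class = position_class,
      atom_frag = t_atom, atom = orig[t_atom]
    )
  }
  if (c_state == "amide") {
    rows[[length(rows) + 1L]] <- tibble(
      residue = tmpl$residue, kind = "cterm_primary_amide", position_class = position_class,
      atom_frag = t_atom, atom = orig[t_atom]
    )
  }
  dplyr::bind_rows(rows)
}

#' Assign canonical pKa values to residue matches
#'
#' Looks up the pKa of every ionizable match in a canonical pKa set,
#' honouring per-residue terminus values and position-dependent side-chain
#' values where the set provides them (Gauci, ProMoST).
#'
#' @param matches A tibble from [match_canonical()].
#' @param set A `pka_set` from [get_pka_set()].
#' @return A tibble of ionizable groups (columns `pka`, `eq_type`, `source`,
#'   `label`, `atom`); non-ionizable matches (Gly side chain, C-terminal
#'   primary amide) contribute no rows.
#' @export
assign_canonical_pkas <- function(matches, set) {
  stopifnot(inherits(set, "pka_set"))
  if (!nrow(matches)) return(.empty_groups())
  out <- list()
  for (i in seq_len(nrow(matches))) {
    row <- matches[i, ]
    if (row$kind == "sidechain") {
      if (!row$residue %in% .IONIZABLE_RESIDUES) next
      out[[length(out) + 1L]] <- .ionizable_group(
        .sidechain_pka(set, row$residue, row$position_class),
        .residue_eq_type(row$residue), "canonical_set",
        sprintf("%s sidechain", row$residue), row$atom
      )
    } else if (row$kind == "nterm_amine") {
      out[[length(out) + 1L]] <- .ionizable_group(
        .terminus_pka(set, "nterm", row$residue), "base", "canonical_set",
        sprintf("N-terminus (%s)", row$residue), row$atom
      )
    } else if (row$kind == "cterm_acid") {
      out[[length(out) + 1L]] <- .ionizable_group(
        .terminus_pka(set, "cterm", row$residue), "acid", "canonical_set",
        sprintf("C-terminus (%s)", row$residue), row$atom
      )
    } # cterm_primary_amide: non-ionizable
  }
  if (!length(out)) return(.empty_groups())
  dplyr::bind_rows(out)
}
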