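# Rule-based pKa prediction for fragments that are not canonical residues:
# an ordered table of substructure rules, each carrying one or two ionizable
# centers. The first rule to match an atom claims it; later rules never
# re-assign a claimed atom. Predicted values outside the admissibility window
# are dropped from the charge model.

#' The shipped pKa prediction rule table
#'
#' @param path Optional path to a rule file in the documented tab-separated
#'   format (see `extdata/pka_rules.tsv`); defaults to the shipped table.
#' @return A data frame of rules in match-precedence order, with compiled
#'   patterns attached.
#' @export
pka_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_cache$rules)) return(.pkg_cache$rules)
    path <- system.file("extdata", "pka_rules.tsv", package = "pepiso", mustWork = TRUE)
    tab <- .read_rules(path)
    .pkg_cache$rules <- tab
    return(tab)
  }
  .read_rules(path)
}

.read_rules <- function(path) {
  tab <- .read_table_file(path)
  stopifnot(all(c("name", "pattern", "c1_pos", "c1_pka", "c1_type") %in% names(tab)))
  tab$compiled <- lapply(tab$pattern, compile_pattern)
  tab
}

#' Predict pKa values of a noncanonical fragment
#'
#' Applies the ordered rule table to a capped fragment. For every rule, in
#' order, and every distinct match, each ionizable center claims its atom; a
#' center whose atom was already claimed (by an earlier rule, a canonical
#' match, or a permanent charge) is skipped. Centers with pKa outside the
#' admissibility window are claimed but not emitted.
#'
#' @param fragment A `pep_fragment` (or `pep_mol`).
#' @param rules A rule table from [pka_rules()].
#' @param window A [pka_window()].
#' @param claimed Integer vector of original-molecule atom indices already
#'   claimed by other sources.
#' @return A tibble of ionizable groups (`source = "predicted"`).
#' @export
predict_pkas <- function(fragment, rules = pka_rules(), window = pka_window(),
                         claimed = integer()) {
  stopifnot(inherits(fragment, "pep_mol"))
  m <- mol_neutralize(fragment)
  orig <- fragment$atoms$orig
  # permanently charged nitrogens are not ionizable centers
  const_local <- which(m$atoms$element == "N" & m$atoms$charge > 0L & m$atoms$nH == 0L)
  claimed_frag <- c(which(!is.na(orig) & orig %in% claimed), const_local)
  props <- .atom_props(m)
  out <- list()
  for (i in seq_len(nrow(rules))) {
    hits <- .match_impl(rules$compiled[[i]], m, props = props)
    if (!length(hits)) next
    keys <- vapply(hits, function(v) paste(v, collapse = ","), character(1))
    hits <- hits[order(keys)]
    centers <- list(c(pos = rules$c1_pos[i], pka = rules$c1_pka[i], type_acid = rules$c1_type[i] == "acid"))
    if (!is.na(rules$c2_pos[i])) {
      centers[[2]] <- c(pos = rules$c2_pos[i], pka = rules$c2_pka[i], type_acid = rules$c2_type[i] == "acid")
    }
    for (map in hits) {
      for (ctr in centers) {
        a <- map[ctr[["pos"]]]
        if (a %in% claimed_frag || m$atoms$is_cap[a]) next
        claimed_frag <- c(claimed_frag, a)
        eq_type <- if (ctr[["type_acid"]] == 1) "acid" else "base"
        if (!admissible(ctr[["pka"]], eq_type, window)) next
        out[[length(out) + 1L]] <- .ionizable_group(
          ctr[["pka"]], eq_type, "predicted", rules$name[i], orig[a]
        )
      }
    }
  }
  if (!length(out)) return(.empty_groups())
  dplyr::bind_rows(out)
}

#' Detect permanently charged groups
#'
#' Four-valent nitrogens without a dissociable proton — quaternary ammonium
#' and N-alkyl pyridinium cations — contribute a pH-independent charge
#' (`Q_constant` of the net-charge model) instead of a pKa equilibrium.
#'
#' @param m A `pep_mol`.
#' @return A tibble with columns `atom` (original-molecule index) and
#'   `charge` (+1 per center).
#' @export
find_constant_charges <- function(m) {
  stopifnot(inherits(m, "pep_mol"))
  props <- .atom_props(m)
  idx <- which(m$atoms$element == "N" & m$atoms$charge > 0L & m$atoms$nH == 0L &
                 (props$X >= 4L | m$atoms$aromatic))
  tibble(atom = m$atoms$orig[idx], charge = rep(1L, length(idx)))
}
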