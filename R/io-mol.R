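# SMILES and SDF interconversion. OpenBabel (via ChemmineOB) does all SMILES
# reading/writing; the V2000 connection table it emits is parsed here directly
# because formal charges (M CHG) must survive the round trip.

.parse_sdf_v2000 <- function(txt, name = "molecule") {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) abort(sprintf("cannot parse structure record '%s'", name))
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || natoms < 1L) abort(sprintf("cannot parse structure record '%s'", name))
  atom_lines <- lines[5:(4 + natoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  charges <- rep(0L, natoms)
  old_chg <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  old_chg[is.na(old_chg)] <- 0L
  # legacy per-atom charge codes: 1..7 -> +3..-3 (4 = radical, ignored)
  legacy <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  sel <- old_chg %in% c(1L, 2L, 3L, 5L, 6L, 7L)
  charges[sel] <- legacy[as.character(old_chg[sel])]
  bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  if (!is.na(nbonds) && nbonds > 0L) {
    bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- tibble(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    npair <- toks[1]
    if (is.na(npair) || npair < 1L) next
    for (p in seq_len(npair)) {
      charges[toks[2 * p]] <- toks[2 * p + 1]
    }
  }
  # aromatic bond order 4 can appear in third-party SDF files; OpenBabel output
  # is kekulized so this is only a safeguard
  if (any(bonds$order == 4L)) {
    abort(sprintf("record '%s' uses aromatic bond order 4; supply a kekulized structure", name))
  }
  # fold explicit hydrogens into neighbour implicit-H counts (handled by
  # valence re-perception after the H atoms are dropped)
  m <- mol_graph(elements, bonds, charges = charges)
  hs <- which(m$atoms$element == "H")
  if (length(hs)) m <- .mol_edit(m, drop_atoms = hs)
  m$atoms$orig <- seq_len(nrow(m$atoms))
  m
}

.write_sdf_v2000 <- function(m, name = "pepiso") {
  natoms <- nrow(m$atoms); nbonds <- nrow(m$bonds)
  header <- c(name, "  pepiso", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, nbonds)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, m$atoms$element)
  bond_lines <- if (nbonds) sprintf("%3d%3d%3d  0  0  0  0", m$bonds$a1, m$bonds$a2, m$bonds$order) else character(0)
  chg <- which(m$atoms$charge != 0L)
  chg_lines <- character(0)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      chg_lines <- c(chg_lines, paste0(
        "M  CHG", sprintf("%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, m$atoms$charge[grp]), collapse = "")
      ))
    }
  }
  paste(c(header, counts, atom_lines, bond_lines, chg_lines, "M  END", "$$$$"), collapse = "\n")
}

#' Parse a SMILES string into a molecule
#'
#' Uses OpenBabel for SMILES interpretation (kekulization, charges, explicit
#' hydrogens); aromaticity is then re-perceived on the package's own graph.
#'
#' @param smiles A single SMILES string.
#' @param name Record label used in error messages.
#' @return A `pep_mol`.
#' @export
mol_from_smiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  txt <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineOB::convertFormat("SMI", "SDF", source = smiles)
    )),
    error = function(e) ""
  )
  if (!nzchar(txt) || !grepl("V2000", txt, fixed = TRUE)) {
    abort(sprintf("cannot parse SMILES for record '%s'", name))
  }
  .parse_sdf_v2000(txt, name = name)
}

#' Write a molecule as SMILES
#' @param m A `pep_mol`.
#' @return A SMILES string.
#' @export
mol_to_smiles <- function(m) {
  out <- ChemmineOB::convertFormat("SDF", "SMI", source = .write_sdf_v2000(m))
  strsplit(out, "[\t\n ]")[[1]][1]
}

#' Parse the records of an SDF file
#' @param path Path to an SDF (V2000) file.
#' @return A list of `pep_mol` objects, named by their title lines.
#' @export
read_sdf_records <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  blocks <- strsplit(txt, "\\$\\$\\$\\$\\s*")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  out <- list()
  for (i in seq_along(blocks)) {
    nm <- trimws(strsplit(blocks[i], "\n")[[1]][1])
    if (!nzchar(nm)) nm <- sprintf("mol%d", i)
    out[[nm]] <- .parse_sdf_v2000(blocks[i], name = nm)
  }
  out
}
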