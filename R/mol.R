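#' @importFrom tibble tibble as_tibble
#' @importFrom rlang %||% abort
NULL

# Standard bonding valences used to place implicit hydrogens on a kekulized
# heavy-atom graph. S and P are promoted to the next standard valence when the
# drawn bond order sum exceeds the base value (sulfones, phosphates, ...).
.effective_valence <- function(element, charge, bondsum) {
  base <- switch(element,
    C = 4L, N = 3L, P = 3L, O = 2L, S = 2L, B = 3L,
    F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L, 0L
  )
  eff <- if (element %in% c("N", "P", "O", "S")) base + charge else base - abs(charge)
  if (element == "S" && bondsum > eff) eff <- if (bondsum <= 4L + charge) 4L + charge else 6L + charge
  if (element == "P" && bondsum > eff) eff <- 5L + charge
  max(0L, eff)
}

.bondsums <- function(natoms, bonds) {
  bs <- rep(0L, natoms)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bs[bonds$a1[k]] <- bs[bonds$a1[k]] + bonds$order[k]
      bs[bonds$a2[k]] <- bs[bonds$a2[k]] + bonds$order[k]
    }
  }
  bs
}

.adjacency <- function(natoms, bonds) {
  adj <- vector("list", natoms)
  for (i in seq_len(natoms)) adj[[i]] <- integer()
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
      adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
    }
  }
  adj
}

# Connectivity test used by ring perception: are a and b connected when bond k
# is removed?
.connected_without <- function(adj, bonds, k, a, b) {
  seen <- logical(length(adj))
  queue <- a
  seen[a] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if ((v == bonds$a1[k] && w == bonds$a2[k]) || (v == bonds$a2[k] && w == bonds$a1[k])) next
      if (!seen[w]) {
        if (w == b) return(TRUE)
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

# Smallest ring through ring-bond k, as an ordered atom cycle (BFS shortest
# path between the endpoints avoiding the bond itself).
.smallest_ring <- function(adj, bonds, k) {
  a <- bonds$a1[k]; b <- bonds$a2[k]
  prev <- rep(NA_integer_, length(adj))
  seen <- logical(length(adj))
  queue <- a
  seen[a] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if ((v == a && w == b) || (v == b && w == a)) next
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        if (w == b) {
          path <- b
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# Pragmatic per-ring aromaticity: 5/6-membered rings of sp2 C/N/O/S atoms with
# a pi-electron count of 6. An atom doubly bonded within the ring, or to a
# fused ring atom, contributes 1; a heteroatom with no double bond contributes
# its lone pair (2); an exocyclic double bond to a non-ring atom (C=O)
# contributes 0.
.ring_is_aromatic <- function(ring, atoms, bonds, in_any_ring) {
  n <- length(ring)
  if (!(n %in% c(5L, 6L))) return(FALSE)
  pi <- 0L
  for (a in ring) {
    el <- atoms$element[a]
    if (!el %in% c("C", "N", "O", "S")) return(FALSE)
    dbl <- bonds[(bonds$a1 == a | bonds$a2 == a) & bonds$order == 2L, , drop = FALSE]
    partners <- ifelse(dbl$a1 == a, dbl$a2, dbl$a1)
    if (any(partners %in% ring)) {
      pi <- pi + 1L
    } else if (length(partners) && any(in_any_ring[partners])) {
      pi <- pi + 1L # fused-ring double bond (e.g. indole junction)
    } else if (length(partners)) {
      if (el == "C") pi <- pi + 0L else pi <- pi + 2L
    } else {
      if (el == "C") return(FALSE) # sp3 carbon breaks the ring
      pi <- pi + 2L
    }
  }
  pi == 6L
}

# Recompute implicit hydrogens, ring membership and aromatic flags. All
# molecule constructors and graph edits funnel through here.
.finalize_mol <- function(atoms, bonds) {
  natoms <- nrow(atoms)
  bonds <- as_tibble(bonds)
  if (!nrow(bonds)) {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer(), aromatic = logical(), in_ring = logical())
  }
  bs <- .bondsums(natoms, bonds)
  atoms$nH <- vapply(seq_len(natoms), function(i) {
    as.integer(max(0L, .effective_valence(atoms$element[i], atoms$charge[i], bs[i]) - bs[i]))
  }, integer(1))
  adj <- .adjacency(natoms, bonds)
  in_ring_bond <- logical(nrow(bonds))
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      in_ring_bond[k] <- .connected_without(adj, bonds, k, bonds$a1[k], bonds$a2[k])
    }
  }
  bonds$in_ring <- in_ring_bond
  atoms$in_ring <- seq_len(natoms) %in% c(bonds$a1[in_ring_bond], bonds$a2[in_ring_bond])
  rings <- list()
  if (any(in_ring_bond)) {
    for (k in which(in_ring_bond)) {
      r <- .smallest_ring(adj, bonds, k)
      if (!is.null(r)) rings[[length(rings) + 1L]] <- r
    }
    keys <- vapply(rings, function(r) paste(sort(r), collapse = ","), character(1))
    rings <- rings[!duplicated(keys)]
  }
  atoms$aromatic <- FALSE
  bonds$aromatic <- FALSE
  for (r in rings) {
    if (.ring_is_aromatic(r, atoms, bonds, atoms$in_ring)) {
      atoms$aromatic[r] <- TRUE
      edge <- cbind(r, c(r[-1], r[1]))
      for (j in seq_len(nrow(edge))) {
        hit <- which((bonds$a1 == edge[j, 1] & bonds$a2 == edge[j, 2]) |
                       (bonds$a1 == edge[j, 2] & bonds$a2 == edge[j, 1]))
        bonds$aromatic[hit] <- TRUE
      }
    }
  }
  m <- list(atoms = atoms, bonds = bonds, rings = rings)
  class(m) <- "pep_mol"
  m
}

#' Build a molecule from an explicit heavy-atom graph
#'
#' Constructs the molecular-graph container used throughout the package from
#' element symbols, formal charges and a bond list. Implicit hydrogen counts,
#' ring membership and aromaticity are perceived automatically from the
#' kekulized graph.
#'
#' @param elements Character vector of element symbols, one per heavy atom.
#' @param bonds Data frame with columns `a1`, `a2` (1-based atom indices) and
#'   `order` (1, 2 or 3).
#' @param charges Integer vector of formal charges (recycled scalar allowed).
#' @param is_cap Logical vector flagging atoms introduced as fragmentation
#'   caps; defaults to `FALSE`.
#' @param orig Integer vector mapping each atom back to an atom of a parent
#'   molecule (`NA` for cap atoms). Defaults to the atom's own index.
#' @return An object of class `pep_mol`.
#' @export
mol_graph <- function(elements, bonds, charges = 0L, is_cap = FALSE, orig = NULL) {
  n <- length(elements)
  charges <- as.integer(rep_len(charges, n))
  is_cap <- rep_len(is_cap, n)
  orig <- orig %||% seq_len(n)
  if (is.null(bonds) || (is.data.frame(bonds) && !nrow(bonds))) {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  bonds <- as_tibble(bonds)
  bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.integer(bonds$order)
  if (nrow(bonds) && (any(bonds$a1 < 1L | bonds$a1 > n) || any(bonds$a2 < 1L | bonds$a2 > n))) {
    abort("bond indices out of range")
  }
  atoms <- tibble(
    element = as.character(elements), charge = charges,
    nH = 0L, aromatic = FALSE, in_ring = FALSE,
    is_cap = is_cap, orig = as.integer(orig)
  )
  .finalize_mol(atoms, bonds)
}

#' @export
print.pep_mol <- function(x, ...) {
  cat(sprintf("<pep_mol> %d heavy atoms, %d bonds, formula %s\n",
              nrow(x$atoms), nrow(x$bonds), mol_formula(x)))
  invisible(x)
}

#' Molecular formula of the heavy-atom graph (implicit H included)
#' @param m A `pep_mol`.
#' @return A character scalar such as `"C6H13NO2"`.
#' @export
mol_formula <- function(m) {
  counts <- table(m$atoms$element)
  h <- sum(m$atoms$nH)
  els <- sort(names(counts))
  els <- c(intersect(c("C"), els), setdiff(els, "C"))
  parts <- character(0)
  for (e in els) {
    parts <- c(parts, paste0(e, if (counts[[e]] > 1) counts[[e]] else ""))
    if (e == "C" && h > 0) parts <- c(parts, paste0("H", if (h > 1) h else ""))
  }
  if (!"C" %in% els && h > 0) parts <- c(parts, paste0("H", if (h > 1) h else ""))
  paste(parts, collapse = "")
}

.mol_neighbors <- function(m) .adjacency(nrow(m$atoms), m$bonds)

.bond_between <- function(m, a, b) {
  which((m$bonds$a1 == a & m$bonds$a2 == b) | (m$bonds$a1 == b & m$bonds$a2 == a))
}

# Edit a molecule: drop bonds (by index), append atoms and bonds, then
# re-perceive hydrogens/rings/aromaticity.
.mol_edit <- function(m, drop_bonds = integer(), add_atoms = NULL, add_bonds = NULL,
                      drop_atoms = integer(), set_charge = NULL) {
  atoms <- m$atoms
  bonds <- m$bonds
  if (!is.null(set_charge)) atoms$charge[set_charge$atom] <- as.integer(set_charge$charge)
  if (length(drop_bonds)) bonds <- bonds[-drop_bonds, , drop = FALSE]
  if (!is.null(add_atoms) && nrow(add_atoms)) {
    add <- tibble(
      element = add_atoms$element,
      charge = as.integer(add_atoms$charge %||% 0L),
      nH = 0L, aromatic = FALSE, in_ring = FALSE,
      is_cap = add_atoms$is_cap %||% FALSE,
      orig = as.integer(add_atoms$orig %||% NA_integer_)
    )
    atoms <- dplyr::bind_rows(atoms, add)
  }
  if (!is.null(add_bonds) && nrow(add_bonds)) {
    bonds <- dplyr::bind_rows(bonds, tibble(
      a1 = as.integer(add_bonds$a1), a2 = as.integer(add_bonds$a2),
      order = as.integer(add_bonds$order), aromatic = FALSE, in_ring = FALSE
    ))
  }
  if (length(drop_atoms)) {
    keep <- setdiff(seq_len(nrow(atoms)), drop_atoms)
    remap <- rep(NA_integer_, nrow(atoms))
    remap[keep] <- seq_along(keep)
    atoms <- atoms[keep, , drop = FALSE]
    bonds <- bonds[!(bonds$a1 %in% drop_atoms) & !(bonds$a2 %in% drop_atoms), , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  }
  .finalize_mol(atoms, bonds)
}

# Connected components of the molecular graph, as a list of atom-index vectors
# ordered by their smallest member.
.mol_components <- function(m) {
  n <- nrow(m$atoms)
  adj <- .mol_neighbors(m)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  split(seq_len(n), comp)
}

# Extract the sub-molecule induced by `atoms_keep` (indices into m).
.mol_subset <- function(m, atoms_keep) {
  atoms_keep <- sort(atoms_keep)
  remap <- rep(NA_integer_, nrow(m$atoms))
  remap[atoms_keep] <- seq_along(atoms_keep)
  atoms <- m$atoms[atoms_keep, , drop = FALSE]
  bonds <- m$bonds[m$bonds$a1 %in% atoms_keep & m$bonds$a2 %in% atoms_keep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  .finalize_mol(atoms, bonds)
}

#' Standardize drawn ionization states to the neutral reference form
#'
#' Protonated sp3 amines (`N+` carrying at least one hydrogen and no multiple
#' bond), deprotonated oxy-/thio-acids (`O-`, `S-` not part of a zwitterionic
#' pair such as a nitro group) and amide anions are converted to their neutral
#' forms so that salt forms and neutral forms of the same molecule match the
#' same substructure templates. Ambiguous centers (aromatic or conjugated
#' cations such as imidazolium and guanidinium, hydrogen-free quaternary
#' nitrogen) are left as drawn.
#'
#' @param m A `pep_mol`.
#' @return A `pep_mol` with the same atom ordering.
#' @export
mol_neutralize <- function(m) {
  atoms <- m$atoms
  bonds <- m$bonds
  adj <- .mol_neighbors(m)
  changed <- FALSE
  for (i in seq_len(nrow(atoms))) {
    el <- atoms$element[i]; q <- atoms$charge[i]
    if (q == 0L) next
    multi <- any(bonds$order[bonds$a1 == i | bonds$a2 == i] > 1L) || atoms$aromatic[i]
    if (el == "N" && q > 0L && atoms$nH[i] >= 1L && !multi) {
      atoms$charge[i] <- 0L; changed <- TRUE
    } else if (el %in% c("O", "S") && q < 0L && !multi) {
      nb_charges <- atoms$charge[adj[[i]]]
      if (!any(nb_charges > 0L)) { # skip nitro / N-oxide style pairs
        atoms$charge[i] <- 0L; changed <- TRUE
      }
    } else if (el == "N" && q < 0L && !multi) {
      atoms$charge[i] <- 0L; changed <- TRUE
    }
  }
  if (!changed) return(m)
  .finalize_mol(atoms, bonds)
}
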