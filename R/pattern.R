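# A compact substructure-query engine over pep_mol graphs. The dialect is the
# subset of SMARTS the shipped template and rule tables use:
#   atoms    C N O S P B F Cl Br I (aliphatic), c n o s (aromatic), *
#   brackets [ ... ] with primitives: element symbols, a/A (aromatic flag),
#            Hn (total H count, default 1), Xn (total connections incl. H),
#            R / R0 (ring membership), +n / -n (formal charge), #n (atomic
#            number), ! (negation), $(...) (recursive environment anchored at
#            the atom), and the connectives & (and), , (or), ; (low-prec and)
#   bonds    default (single-or-aromatic), - = # ~ :
#   branches ( ... ), ring closures 1-9
# No stereo, no wildcard charge ranges, no component-level operators.

.pkg_cache <- new.env(parent = emptyenv())

.atomic_symbols <- c(`5` = "B", `6` = "C", `7` = "N", `8` = "O", `9` = "F",
                     `15` = "P", `16` = "S", `17` = "Cl", `35` = "Br", `53` = "I")

.parse_bracket <- function(body, pattern_string) {
  groups <- list()
  alts <- list()
  prims <- list()
  i <- 1L
  n <- nchar(body)
  neg <- FALSE
  push_prim <- function(kind, value, aromatic = NA) {
    prims[[length(prims) + 1L]] <<- list(kind = kind, value = value, aromatic = aromatic, negate = neg)
    neg <<- FALSE
  }
  close_alt <- function() {
    if (length(prims)) alts[[length(alts) + 1L]] <<- prims
    prims <<- list()
  }
  close_group <- function() {
    close_alt()
    if (length(alts)) groups[[length(groups) + 1L]] <<- alts
    alts <<- list()
  }
  read_digits <- function() {
    d <- ""
    while (i <= n && grepl("[0-9]", substr(body, i, i))) {
      d <- paste0(d, substr(body, i, i)); i <<- i + 1L
    }
    d
  }
  while (i <= n) {
    ch <- substr(body, i, i)
    two <- substr(body, i, i + 1L)
    if (ch == ";") { close_group(); i <- i + 1L }
    else if (ch == ",") { close_alt(); i <- i + 1L }
    else if (ch == "&") { i <- i + 1L }
    else if (ch == "!") { neg <- TRUE; i <- i + 1L }
    else if (two == "$(") {
      depth <- 1L; j <- i + 2L
      while (j <= n && depth > 0L) {
        cj <- substr(body, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) abort(sprintf("unbalanced $() in pattern '%s'", pattern_string))
      inner <- substr(body, i + 2L, j - 2L)
      push_prim("recursive", compile_pattern(inner))
      i <- j
    }
    else if (two %in% c("Cl", "Br")) { push_prim("element", two, aromatic = FALSE); i <- i + 2L }
    else if (ch %in% c("C", "N", "O", "S", "P", "B", "F", "I")) {
      push_prim("element", ch, aromatic = FALSE); i <- i + 1L
    }
    else if (ch %in% c("c", "n", "o", "s")) {
      push_prim("element", toupper(ch), aromatic = TRUE); i <- i + 1L
    }
    else if (ch == "a") { push_prim("aromatic", TRUE); i <- i + 1L }
    else if (ch == "A") { push_prim("aromatic", FALSE); i <- i + 1L }
    else if (ch == "*") { push_prim("any", TRUE); i <- i + 1L }
    else if (ch == "H") {
      i <- i + 1L; d <- read_digits()
      push_prim("nH", if (nzchar(d)) as.integer(d) else 1L)
    }
    else if (ch == "X") {
      i <- i + 1L; d <- read_digits()
      if (!nzchar(d)) abort(sprintf("X needs a digit in pattern '%s'", pattern_string))
      push_prim("X", as.integer(d))
    }
    else if (ch == "R") {
      i <- i + 1L; d <- read_digits()
      push_prim("ring", !(nzchar(d) && d == "0"))
    }
    else if (ch == "#") {
      i <- i + 1L; d <- read_digits()
      sym <- .atomic_symbols[d]
      if (is.na(sym)) abort(sprintf("unsupported atomic number #%s in pattern '%s'", d, pattern_string))
      push_prim("element", unname(sym), aromatic = NA)
    }
    else if (ch %in% c("+", "-")) {
      sign <- if (ch == "+") 1L else -1L
      cnt <- 1L; i <- i + 1L
      while (i <= n && substr(body, i, i) == ch) { cnt <- cnt + 1L; i <- i + 1L }
      d <- read_digits()
      if (nzchar(d)) cnt <- as.integer(d)
      push_prim("charge", sign * cnt)
    }
    else if (grepl("[0-9]", ch)) { i <- i + 1L } # isotope labels: ignored
    else abort(sprintf("cannot parse '%s' in pattern '%s'", ch, pattern_string))
  }
  close_group()
  if (!length(groups)) abort(sprintf("empty bracket atom in pattern '%s'", pattern_string))
  groups
}

# one-primitive atom expressions for bare (unbracketed) atoms
.bare_atom <- function(element, aromatic) {
  list(list(list(list(kind = "element", value = element, aromatic = aromatic, negate = FALSE))))
}

#' Compile a substructure pattern
#'
#' Parses a pattern written in the package's SMARTS subset (see the data file
#' headers under `extdata` for the dialect) into a matchable query graph.
#' Compiled patterns are cached by their string.
#'
#' @param s Pattern string.
#' @return An object of class `pep_pattern`.
#' @export
compile_pattern <- function(s) {
  key <- paste0("pat:", s)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  atoms <- list()
  bonds <- list()
  ring_open <- list()
  prev <- NA_integer_
  stack <- integer()
  pending_bond <- "default"
  i <- 1L
  n <- nchar(s)
  add_atom <- function(expr) {
    atoms[[length(atoms) + 1L]] <<- expr
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = idx, type = pending_bond)
    }
    pending_bond <<- "default"
    prev <<- idx
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    two <- substr(s, i, i + 1L)
    if (ch == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        cj <- substr(s, j, j)
        if (cj == "[") depth <- depth + 1L
        if (cj == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) abort(sprintf("unbalanced [] in pattern '%s'", s))
      add_atom(.parse_bracket(substr(s, i + 1L, j - 2L), s))
      i <- j
    }
    else if (two %in% c("Cl", "Br")) { add_atom(.bare_atom(two, FALSE)); i <- i + 2L }
    else if (ch %in% c("C", "N", "O", "S", "P", "B", "F", "I")) { add_atom(.bare_atom(ch, FALSE)); i <- i + 1L }
    else if (ch %in% c("c", "n", "o", "s")) { add_atom(.bare_atom(toupper(ch), TRUE)); i <- i + 1L }
    else if (ch == "*") { add_atom(list(list(list(list(kind = "any", value = TRUE, aromatic = NA, negate = FALSE))))); i <- i + 1L }
    else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (!length(stack)) abort(sprintf("unbalanced () in pattern '%s'", s))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    }
    else if (ch %in% c("-", "=", "#", "~", ":")) {
      pending_bond <- switch(ch, `-` = "single", `=` = "double", `#` = "triple", `~` = "any", `:` = "aromatic")
      i <- i + 1L
    }
    else if (grepl("[1-9]", ch)) {
      if (!is.null(ring_open[[ch]])) {
        op <- ring_open[[ch]]
        btype <- if (pending_bond != "default") pending_bond else op$type
        bonds[[length(bonds) + 1L]] <- list(a1 = op$atom, a2 = prev, type = btype)
        ring_open[[ch]] <- NULL
        pending_bond <- "default"
      } else {
        ring_open[[ch]] <- list(atom = prev, type = pending_bond)
        pending_bond <- "default"
      }
      i <- i + 1L
    }
    else abort(sprintf("cannot parse '%s' in pattern '%s'", ch, s))
  }
  if (!length(atoms)) abort(sprintf("empty pattern '%s'", s))
  pat <- list(string = s, atoms = atoms,
              bonds = if (length(bonds)) dplyr::bind_rows(lapply(bonds, as_tibble)) else
                tibble(a1 = integer(), a2 = integer(), type = character()))
  class(pat) <- "pep_pattern"
  .pkg_cache[[key]] <- pat
  pat
}

.atom_props <- function(m) {
  deg <- rep(0L, nrow(m$atoms))
  if (nrow(m$bonds)) {
    t1 <- table(factor(m$bonds$a1, levels = seq_len(nrow(m$atoms))))
    t2 <- table(factor(m$bonds$a2, levels = seq_len(nrow(m$atoms))))
    deg <- as.integer(t1 + t2)
  }
  list(element = m$atoms$element, aromatic = m$atoms$aromatic,
       nH = m$atoms$nH, X = deg + m$atoms$nH,
       ring = m$atoms$in_ring, charge = m$atoms$charge)
}

.eval_primitive <- function(p, m, props, a) {
  val <- switch(p$kind,
    element = props$element[a] == p$value &&
      (is.na(p$aromatic) || props$aromatic[a] == p$aromatic),
    aromatic = props$aromatic[a] == p$value,
    nH = props$nH[a] == p$value,
    X = props$X[a] == p$value,
    ring = props$ring[a] == p$value,
    charge = props$charge[a] == p$value,
    any = TRUE,
    recursive = length(.match_impl(p$value, m, props, anchor = a, max_matches = 1L)) > 0L
  )
  if (isTRUE(p$negate)) !val else val
}

.eval_atom <- function(expr, m, props, a) {
  for (group in expr) {
    ok <- FALSE
    for (alt in group) {
      if (all(vapply(alt, .eval_primitive, logical(1), m = m, props = props, a = a))) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

.eval_bond <- function(type, order, aromatic) {
  switch(type,
    default = (order == 1L && !aromatic) || aromatic,
    single = order == 1L && !aromatic,
    double = order == 2L && !aromatic,
    triple = order == 3L,
    aromatic = aromatic,
    any = TRUE
  )
}

# DFS ordering of pattern atoms: each atom after the first enters via a parent
# bond; remaining pattern bonds become closure constraints.
.pattern_plan <- function(pat) {
  np <- length(pat$atoms)
  order <- 1L
  parent <- rep(NA_integer_, np)
  parent_bond <- rep(NA_integer_, np)
  visited <- c(TRUE, rep(FALSE, np - 1L))
  seq_atoms <- 1L
  repeat {
    progress <- FALSE
    for (b in seq_len(nrow(pat$bonds))) {
      a1 <- pat$bonds$a1[b]; a2 <- pat$bonds$a2[b]
      if (visited[a1] && !visited[a2]) {
        visited[a2] <- TRUE; parent[a2] <- a1; parent_bond[a2] <- b
        seq_atoms <- c(seq_atoms, a2); progress <- TRUE
      } else if (visited[a2] && !visited[a1]) {
        visited[a1] <- TRUE; parent[a1] <- a2; parent_bond[a1] <- b
        seq_atoms <- c(seq_atoms, a1); progress <- TRUE
      }
    }
    if (!progress) break
  }
  if (!all(visited)) abort(sprintf("pattern '%s' is not connected", pat$string))
  closures <- setdiff(seq_len(nrow(pat$bonds)), parent_bond[!is.na(parent_bond)])
  list(seq_atoms = seq_atoms, parent = parent, parent_bond = parent_bond, closures = closures)
}

.match_impl <- function(pat, m, props = NULL, anchor = NULL, max_matches = Inf, unique_sets = FALSE) {
  props <- props %||% .atom_props(m)
  plan <- .pattern_plan(pat)
  np <- length(pat$atoms)
  nt <- nrow(m$atoms)
  # adjacency with bond rows
  adjb <- vector("list", nt)
  for (i in seq_len(nt)) adjb[[i]] <- list()
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      a1 <- m$bonds$a1[k]; a2 <- m$bonds$a2[k]
      adjb[[a1]][[length(adjb[[a1]]) + 1L]] <- c(a2, k)
      adjb[[a2]][[length(adjb[[a2]]) + 1L]] <- c(a1, k)
    }
  }
  results <- list()
  seen_sets <- character(0)
  assign_vec <- rep(NA_integer_, np)
  used <- logical(nt)
  recurse <- function(step) {
    if (length(results) >= max_matches) return()
    if (step > np) {
      map <- assign_vec
      if (unique_sets) {
        key <- paste(sort(map), collapse = ",")
        if (key %in% seen_sets) return()
        seen_sets <<- c(seen_sets, key)
      }
      results[[length(results) + 1L]] <<- map
      return()
    }
    pa <- plan$seq_atoms[step]
    if (step == 1L) {
      cands <- if (!is.null(anchor)) anchor else seq_len(nt)
      for (t in cands) {
        if (used[t] || !.eval_atom(pat$atoms[[pa]], m, props, t)) next
        assign_vec[pa] <<- t; used[t] <<- TRUE
        recurse(step + 1L)
        used[t] <<- FALSE; assign_vec[pa] <<- NA_integer_
        if (length(results) >= max_matches) return()
      }
      return()
    }
    from <- assign_vec[plan$parent[pa]]
    btype <- pat$bonds$type[plan$parent_bond[pa]]
    for (nb in adjb[[from]]) {
      t <- nb[1]; k <- nb[2]
      if (used[t]) next
      if (!.eval_bond(btype, m$bonds$order[k], m$bonds$aromatic[k])) next
      if (!.eval_atom(pat$atoms[[pa]], m, props, t)) next
      ok <- TRUE
      for (cb in plan$closures) {
        pa1 <- pat$bonds$a1[cb]; pa2 <- pat$bonds$a2[cb]
        if ((pa1 == pa && !is.na(assign_vec[pa2])) || (pa2 == pa && !is.na(assign_vec[pa1]))) {
          other <- if (pa1 == pa) assign_vec[pa2] else assign_vec[pa1]
          kk <- .bond_between(m, t, other)
          if (!length(kk) || !.eval_bond(pat$bonds$type[cb], m$bonds$order[kk[1]], m$bonds$aromatic[kk[1]])) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      assign_vec[pa] <<- t; used[t] <<- TRUE
      recurse(step + 1L)
      used[t] <<- FALSE; assign_vec[pa] <<- NA_integer_
      if (length(results) >= max_matches) return()
    }
  }
  recurse(1L)
  results
}

#' Find substructure matches of a pattern in a molecule
#'
#' @param m A `pep_mol`.
#' @param pattern A pattern string (in the package's SMARTS subset) or a
#'   compiled `pep_pattern`.
#' @param unique_sets If `TRUE`, symmetry-equivalent matches mapping to the
#'   same atom set are collapsed to one (OpenBabel-style unique matching).
#' @return A list of integer vectors; element `i` of a vector is the molecule
#'   atom matched by pattern atom `i`. Matches are returned in a deterministic
#'   order (sorted by their atom assignment).
#' @export
match_pattern <- function(m, pattern, unique_sets = FALSE) {
  pat <- if (inherits(pattern, "pep_pattern")) pattern else compile_pattern(pattern)
  res <- .match_impl(pat, m, unique_sets = unique_sets)
  if (length(res) > 1L) {
    keys <- vapply(res, function(v) paste(v, collapse = ","), character(1))
    res <- res[order(keys)]
  }
  res
}
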