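# Canonical pKa knowledge: the eight published pKa sets for the termini and
# the seven ionizable side chains, plus the global admissibility windows that
# keep predicted pKa values inside the experimentally meaningful pH range.


# Read a tab-separated data file whose header comments start with '#'.
# comment.char cannot be used: patterns legitimately contain '#'.
.read_table_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  utils::read.delim(text = paste(lines, collapse = "\n"), stringsAsFactors = FALSE,
                    na.strings = "NA")
}

.IONIZABLE_RESIDUES <- c("C", "Y", "D", "E", "H", "K", "R")
.ACID_RESIDUES <- c("C", "D", "E", "Y")
.BASE_RESIDUES <- c("H", "K", "R")
.PKA_SET_ORDER <- c("IPC_peptide", "IPC2_peptide", "Gauci", "Grimsley",
                    "Toseland", "Thurlkill", "Lehninger", "ProMoST")

#' Read pKa sets from a tabular data file
#'
#' The shipped file `extdata/pka_sets.tsv` documents the format: one row per
#' pKa value with columns `set`, `parameter` (`nterm`/`cterm`/`sidechain`),
#' `residue` (`*` for the set default), `position`
#' (`any`/`n_terminal`/`internal`/`c_terminal`) and `pka`. User-defined sets
#' in the same format can be loaded and passed to the consensus functions.
#'
#' @param path Path to a tab-separated file in the documented format.
#' @return A named list of `pka_set` objects, in file order.
#' @export
read_pka_sets <- function(path) {
  raw <- .read_table_file(path)
  stopifnot(all(c("set", "parameter", "residue", "position", "pka") %in% names(raw)))
  out <- list()
  for (nm in unique(raw$set)) {
    d <- raw[raw$set == nm, , drop = FALSE]
    term <- function(par) {
      dd <- d[d$parameter == par, , drop = FALSE]
      default <- dd$pka[dd$residue == "*"]
      if (length(default) != 1L) abort(sprintf("set '%s' needs exactly one %s default", nm, par))
      by_res <- dd[dd$residue != "*", , drop = FALSE]
      list(default = default, by_residue = stats::setNames(by_res$pka, by_res$residue))
    }
    nt <- term("nterm"); ct <- term("cterm")
    sc <- d[d$parameter == "sidechain", , drop = FALSE]
    flat <- sc[sc$position == "any", , drop = FALSE]
    pos <- sc[sc$position != "any", , drop = FALSE]
    positional <- NULL
    if (nrow(pos)) {
      positional <- lapply(split(pos, pos$residue), function(x) stats::setNames(x$pka, x$position))
    }
    sidechain <- stats::setNames(flat$pka, flat$residue)
    if (is.null(positional) && !setequal(names(sidechain), .IONIZABLE_RESIDUES)) {
      abort(sprintf("set '%s' must cover side chains %s", nm, paste(.IONIZABLE_RESIDUES, collapse = "")))
    }
    s <- list(name = nm,
              nterm_default = nt$default, nterm_by_residue = nt$by_residue,
              cterm_default = ct$default, cterm_by_residue = ct$by_residue,
              sidechain = sidechain, positional_sidechain = positional)
    class(s) <- "pka_set"
    out[[nm]] <- s
  }
  out
}

.builtin_pka_sets <- function() {
  if (is.null(.pkg_cache$pka_sets)) {
    path <- system.file("extdata", "pka_sets.tsv", package = "pepiso", mustWork = TRUE)
    sets <- read_pka_sets(path)
    .pkg_cache$pka_sets <- sets[.PKA_SET_ORDER]
  }
  .pkg_cache$pka_sets
}

#' List the shipped canonical pKa sets
#'
#' @return Character vector of the eight set identifiers, in a fixed order.
#' @export
list_pka_sets <- function() names(.builtin_pka_sets())

#' Retrieve a shipped canonical pKa set
#'
#' @param name One of the identifiers returned by [list_pka_sets()].
#' @return A `pka_set` object: terminus defaults, optional per-residue
#'   terminus values, the seven side-chain pKa values and, for ProMoST,
#'   position-dependent side-chain values.
#' @export
get_pka_set <- function(name) {
  sets <- .builtin_pka_sets()
  if (!name %in% names(sets)) {
    abort(sprintf("unknown pKa set '%s'; valid names are: %s",
                  name, paste(names(sets), collapse = ", ")))
  }
  sets[[name]]
}

#' @export
print.pka_set <- function(x, ...) {
  cat(sprintf("<pka_set> %s: N-term %.3g, C-term %.3g; side chains %s\n",
              x$name, x$nterm_default, x$cterm_default,
              paste(sprintf("%s=%.3g", names(x$sidechain), x$sidechain), collapse = " ")))
  invisible(x)
}

#' The pKa admissibility window
#'
#' Predicted pKa values outside the experimentally relevant range are dropped
#' from the charge model: acids must have pKa below 12 (and at least -5),
#' bases above 2 (and at most 15). The wide outer limits keep strong but
#' relevant groups (sulfates, guanidines) in the calculation.
#'
#' @param acid_lower,acid_upper,base_lower,base_upper Window edges in pH units.
#' @return A `pka_window` object.
#' @export
pka_window <- function(acid_lower = -5, acid_upper = 12, base_lower = 2, base_upper = 15) {
  stopifnot(acid_lower < acid_upper, base_lower < base_upper)
  structure(list(acid_lower = acid_lower, acid_upper = acid_upper,
                 base_lower = base_lower, base_upper = base_upper),
            class = "pka_window")
}

#' Is a predicted pKa inside the admissibility window?
#'
#' @param pka pKa value (pH units).
#' @param eq_type `"acid"` or `"base"`.
#' @param window A [pka_window()].
#' @return Logical: `TRUE` when the value is kept in the charge model. The
#'   primary bounds are strict (acids strictly below 12, bases strictly above
#'   2); the outer guards are inclusive.
#' @export
admissible <- function(pka, eq_type, window = pka_window()) {
  eq_type <- match.arg(eq_type, c("acid", "base"))
  if (eq_type == "acid") pka >= window$acid_lower & pka < window$acid_upper
  else pka > window$base_lower & pka <= window$base_upper
}

# Canonical look-ups used by both structure and sequence mode --------------

.terminus_pka <- function(set, which, residue) {
  slot <- if (which == "nterm") list(set$nterm_by_residue, set$nterm_default)
          else list(set$cterm_by_residue, set$cterm_default)
  v <- slot[[1]][residue]
  if (length(v) == 1L && !is.na(v)) unname(v) else slot[[2]]
}

.sidechain_pka <- function(set, residue, position_class) {
  if (!is.null(set$positional_sidechain) && residue %in% names(set$positional_sidechain)) {
    v <- set$positional_sidechain[[residue]][position_class]
    if (!is.na(v)) return(unname(v))
  }
  unname(set$sidechain[residue])
}

.residue_eq_type <- function(residue) {
  if (residue %in% .ACID_RESIDUES) "acid" else "base"
}

# A uniform container for one acid/base equilibrium.
.ionizable_group <- function(pka, eq_type, source, label, atom = NA_integer_) {
  tibble(pka = as.numeric(pka), eq_type = eq_type, source = source,
         label = label, atom = as.integer(atom))
}

.empty_groups <- function() {
  tibble(pka = numeric(), eq_type = character(), source = character(),
         label = character(), atom = integer())
}
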