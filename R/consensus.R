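# Full structure pipeline and the consensus result object: fragment, match,
# assign canonical pKa values once per published set, predict pKa for
# noncanonical fragments (identical across sets), then solve for pI per set
# and aggregate mean +/- SD, charge at a reporting pH and the isoelectric
# interval.

# Run fragmentation + matching once; only the per-set canonical look-up
# differs between pKa sets.
.structure_groups <- function(m) {
  const <- find_constant_charges(m)
  frags <- cleave_and_cap(m)
  canonical <- list()
  predicted <- list()
  claimed <- const$atom
  for (f in frags) {
    mm <- match_canonical(f)
    if (nrow(mm)) {
      canonical[[length(canonical) + 1L]] <- mm
      claimed <- union(claimed, mm$atom[!is.na(mm$atom)])
    } else {
      pg <- predict_pkas(f, claimed = claimed)
      if (nrow(pg)) {
        predicted[[length(predicted) + 1L]] <- pg
        claimed <- union(claimed, pg$atom[!is.na(pg$atom)])
      }
    }
  }
  list(
    canonical = canonical,
    predicted = if (length(predicted)) dplyr::bind_rows(predicted) else .empty_groups(),
    q_constant = sum(const$charge),
    n_fragments = length(frags)
  )
}

.resolve_sets <- function(sets) {
  if (is.null(sets)) sets <- list_pka_sets()
  if (is.character(sets)) sets <- lapply(sets, get_pka_set)
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

# Aggregate per-set pI solutions into a pi_result.
.aggregate_pi <- function(groups_by_set, q_constant, input, mode, ph_charge = 7.4) {
  rows <- list()
  for (nm in names(groups_by_set)) {
    g <- groups_by_set[[nm]]
    sol <- solve_pi(g, q_constant)
    ival <- isoelectric_interval(g, q_constant)
    rows[[nm]] <- tibble(
      set = nm,
      pi = if (sol$status == "defined") sol$pi else NA_real_,
      status = sol$status,
      touch_ph = if (sol$status == "asymptotic_touch") sol$pi else NA_real_,
      q_at_ph = net_charge(ph_charge, g, q_constant),
      interval_low = if (is.null(ival)) NA_real_ else ival[["ph_low"]],
      interval_high = if (is.null(ival)) NA_real_ else ival[["ph_high"]],
      n_groups = nrow(g),
      groups = list(g)
    )
  }
  per_set <- dplyr::bind_rows(rows)
  defined <- per_set$pi[!is.na(per_set$pi)]
  pi_mean <- if (length(defined)) mean(defined) else NA_real_
  pi_sd <- if (length(defined)) sqrt(mean((defined - pi_mean)^2)) else NA_real_
  statuses <- unique(per_set$status)
  status <- if (length(statuses) == 1L) statuses else if ("defined" %in% statuses) "defined" else statuses[1]
  res <- list(
    input = input, mode = mode, ph_charge = ph_charge,
    per_set = per_set, q_constant = q_constant,
    pi_mean = pi_mean, pi_sd = pi_sd, n_defined = length(defined),
    interval = c(ph_low = mean(per_set$interval_low[!is.na(per_set$interval_low)]),
                 ph_high = mean(per_set$interval_high[!is.na(per_set$interval_high)])),
    q_mean = mean(per_set$q_at_ph),
    status = status
  )
  class(res) <- "pi_result"
  res
}

#' Consensus isoelectric point of a chemical structure
#'
#' Runs the full structure-based workflow: cleave all backbone amide bonds
#' and cap the fragments, match canonical residues and assign their pKa
#' values from each published set, predict pKa values of noncanonical
#' fragments with the rule table (these are identical across sets), detect
#' permanently charged nitrogens, and solve the Henderson-Hasselbalch charge
#' equation per set. The consensus pI is reported as mean and standard
#' deviation over the sets with a defined pI.
#'
#' @param m A `pep_mol`, or a SMILES string.
#' @param sets Character vector of pKa set names, or a list of `pka_set`
#'   objects; defaults to all eight shipped sets.
#' @param ph_charge Reporting pH for the net charge (default 7.4).
#' @return A `pi_result` object; see [tidy.pi_result()] and
#'   [glance.pi_result()].
#' @export
pi_consensus <- function(m, sets = NULL, ph_charge = 7.4) {
  input <- if (is.character(m)) m else "structure"
  if (is.character(m)) m <- mol_from_smiles(m)
  stopifnot(inherits(m, "pep_mol"))
  sets <- .resolve_sets(sets)
  parts <- .structure_groups(m)
  groups_by_set <- lapply(sets, function(s) {
    canon <- lapply(parts$canonical, assign_canonical_pkas, set = s)
    dplyr::bind_rows(c(canon, list(parts$predicted)))
  })
  res <- .aggregate_pi(groups_by_set, parts$q_constant, input, "structure", ph_charge)
  res$n_fragments <- parts$n_fragments
  res
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("<pi_result> %s mode, input: %s\n", x$mode, x$input))
  if (!is.na(x$pi_mean)) {
    cat(sprintf("  pI = %.2f +/- %.2f (over %d of %d pKa sets)\n",
                x$pi_mean, x$pi_sd, x$n_defined, nrow(x$per_set)))
  } else {
    cat(sprintf("  pI undefined (%s)\n", x$status))
  }
  if (!all(is.na(x$interval))) {
    cat(sprintf("  isoelectric interval (|Q| <= 0.05 e): %.2f - %.2f\n",
                x$interval[["ph_low"]], x$interval[["ph_high"]]))
  }
  cat(sprintf("  net charge at pH %.1f: %+.2f e", x$ph_charge, x$q_mean))
  if (x$q_constant != 0) cat(sprintf(" (permanent charge %+d)", x$q_constant))
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-set results of a consensus pI calculation
#'
#' @param x A `pi_result`.
#' @param ... Unused.
#' @return A tibble with one row per pKa set: pI, solver status, net charge
#'   at the reporting pH, isoelectric interval edges and group count.
#' @method tidy pi_result
#' @export
tidy.pi_result <- function(x, ...) {
  dplyr::select(x$per_set, -"groups")
}

#' One-row summary of a consensus pI calculation
#'
#' @param x A `pi_result`.
#' @param ... Unused.
#' @return A one-row tibble: consensus mean and SD, number of defined sets,
#'   mean interval edges, mean charge at the reporting pH and status.
#' @export
glance.pi_result <- function(x, ...) {
  tibble(
    pi_mean = x$pi_mean, pi_sd = x$pi_sd, n_defined = x$n_defined,
    n_sets = nrow(x$per_set),
    interval_low = x$interval[["ph_low"]], interval_high = x$interval[["ph_high"]],
    q_at_ph = x$q_mean, ph_charge = x$ph_charge,
    q_constant = x$q_constant, status = x$status
  )
}

#' Titration-curve plot of a consensus pI calculation
#'
#' Draws the charge versus pH curve for every pKa set, marks the zero-charge
#' line and the per-set pI values.
#'
#' @param object A `pi_result`.
#' @param ph Grid of pH values.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pi_result
#' @export
autoplot.pi_result <- function(object, ph = seq(0, 14, by = 0.05), ...) {
  curves <- purrr::map2_dfr(object$per_set$set, object$per_set$groups, function(nm, g) {
    dplyr::mutate(charge_curve(g, object$q_constant, ph = ph), set = nm)
  })
  pts <- dplyr::filter(tidy(object), !is.na(.data$pi))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$ph, y = .data$q, colour = .data$set)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pH", y = "net charge (e)", colour = "pKa set",
                  title = sprintf("Charge vs pH: %s", object$input))
  if (nrow(pts)) {
    p <- p + ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$pi, y = 0, colour = .data$set),
                                 size = 2, show.legend = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
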