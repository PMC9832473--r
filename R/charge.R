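# The independent-site charge model: each basic group contributes
# 1/(1 + 10^(pH - pKa)) and each acidic group -1/(1 + 10^(pKa - pH)); a
# permanent charge shifts the whole curve. pI is the root of the resulting
# monotone non-increasing Q(pH) on [0, 14], located by bisection with the
# published charge tolerance of 0.01 e.

#' Net molecular charge at a given pH
#'
#' @param ph Numeric vector of pH values.
#' @param groups Tibble of ionizable groups (columns `pka`, `eq_type`).
#' @param q_constant Permanent charge (elementary-charge units).
#' @return Numeric vector of net charges, one per pH value.
#' @export
net_charge <- function(ph, groups, q_constant = 0) {
  bases <- groups$pka[groups$eq_type == "base"]
  acids <- groups$pka[groups$eq_type == "acid"]
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - bases))) - sum(1 / (1 + 10^(acids - p))) + q_constant
  }, numeric(1))
}

#' Charge versus pH curve
#'
#' @inheritParams net_charge
#' @param ph Ascending grid of pH values (default 0 to 14 in steps of 0.1).
#' @return A tibble with columns `ph` and `q`.
#' @export
charge_curve <- function(groups, q_constant = 0, ph = seq(0, 14, by = 0.1)) {
  tibble(ph = ph, q = net_charge(ph, groups, q_constant))
}

#' Solve for the isoelectric point
#'
#' Bisection on the initial interval pH 0-14. When the charge has the same
#' sign at both ends the pI is undefined: if the curve still comes within
#' 0.05 e of zero the molecule "becomes uncharged" asymptotically and the pH
#' of closest approach is reported with status `asymptotic_touch`; otherwise
#' the status is `no_crossing` (only acids, only bases, or neither).
#'
#' @inheritParams net_charge
#' @param tol_charge Charge tolerance at the root (0.01 e).
#' @param tol_ph Interval-width convergence criterion.
#' @param max_iter Bisection iteration cap.
#' @param touch_threshold |Q| threshold for the asymptotic-touch diagnosis.
#' @return A list with elements `pi` (pH units, `NA` when undefined),
#'   `status` (`"defined"`, `"no_crossing"` or `"asymptotic_touch"`) and
#'   `q_at_pi`.
#' @export
solve_pi <- function(groups, q_constant = 0, tol_charge = 0.01, tol_ph = 1e-6,
                     max_iter = 200L, touch_threshold = 0.05) {
  f <- function(p) net_charge(p, groups, q_constant)
  lo <- 0; hi <- 14
  qlo <- f(lo); qhi <- f(hi)
  if (qlo == 0) return(list(pi = lo, status = "defined", q_at_pi = 0))
  if (qhi == 0) return(list(pi = hi, status = "defined", q_at_pi = 0))
  if (sign(qlo) == sign(qhi)) {
    grid <- seq(0, 14, by = 0.01)
    qs <- abs(f(grid))
    i_min <- which.min(qs)
    opt <- stats::optimize(function(p) abs(f(p)),
                           lower = max(0, grid[i_min] - 0.01),
                           upper = min(14, grid[i_min] + 0.01), tol = 1e-8)
    if (opt$objective <= touch_threshold) {
      return(list(pi = opt$minimum, status = "asymptotic_touch", q_at_pi = f(opt$minimum)))
    }
    return(list(pi = NA_real_, status = "no_crossing", q_at_pi = NA_real_))
  }
  iter <- 0L
  while ((hi - lo) > tol_ph && iter < max_iter) {
    mid <- (lo + hi) / 2
    qm <- f(mid)
    if (qm == 0) { lo <- mid; hi <- mid; break }
    if (sign(qm) == sign(qlo)) { lo <- mid; qlo <- qm } else { hi <- mid; qhi <- qm }
    iter <- iter + 1L
  }
  root <- (lo + hi) / 2
  qr <- f(root)
  status <- if (abs(qr) <= tol_charge) "defined" else "asymptotic_touch"
  list(pi = root, status = status, q_at_pi = qr)
}

#' Isoelectric interval
#'
#' The maximal contiguous pH span inside 0-14 where the net charge is
#' negligible (|Q| <= 0.05 e by default). Characterizes flat charge curves
#' whose pI alone is poorly defined.
#'
#' @inheritParams net_charge
#' @param band Half-width of the negligible-charge band (e).
#' @return A numeric vector `c(ph_low, ph_high)`, or `NULL` when the charge
#'   never enters the band.
#' @export
isoelectric_interval <- function(groups, q_constant = 0, band = 0.05) {
  f <- function(p) net_charge(p, groups, q_constant)
  q0 <- f(0); q14 <- f(14)
  # Q is non-increasing: inside the band somewhere iff Q(14) <= band and
  # Q(0) >= -band
  if (q14 > band || q0 < -band) return(NULL)
  lo <- if (q0 <= band) 0 else
    stats::uniroot(function(p) f(p) - band, c(0, 14), tol = 1e-9)$root
  hi <- if (q14 >= -band) 14 else
    stats::uniroot(function(p) f(p) + band, c(0, 14), tol = 1e-9)$root
  c(ph_low = lo, ph_high = hi)
}
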