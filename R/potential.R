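# Torsion potentials, harmonic boosts, and analytic state probabilities.

#' Boltzmann constant in kcal/(mol K)
#'
#' Gas constant expressed per molecule-mole in kcal, the conventional value
#' used by biomolecular force fields.
#' @export
kB <- 0.0019872041

#' Wrap angles into (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @examples
#' wrap_angle(c(270, -180, 540))
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  # x %% 360 maps -180 to 180, so the result lies in (-180, 180]
  w
}

#' Cosine-series torsion term
#'
#' One term of an Amber-form torsion potential,
#' \eqn{U_n(\omega) = (V_n/2)(1 + \cos(n\omega - \gamma_n))}.
#'
#' @param n Multiplicity (positive integer).
#' @param V Barrier coefficient \eqn{V_n} in kcal/mol, non-negative.
#' @param gamma Phase \eqn{\gamma_n} in degrees.
#' @return An object of class \code{torsion_term}.
#' @export
torsion_term <- function(n, V, gamma = 0) {
  stopifnot(length(n) == 1, length(V) == 1, length(gamma) == 1)
  if (!is.finite(n) || n < 1 || n != round(n)) {
    stop("multiplicity 'n' must be a positive integer")
  }
  if (!is.finite(V) || V < 0) stop("'V' must be finite and >= 0")
  structure(list(n = as.integer(n), V = V, gamma = gamma),
            class = "torsion_term")
}

#' Harmonic boost specification
#'
#' Gaussian-accelerated-MD style boost applied below an energy threshold:
#' \eqn{\Delta V(\omega) = \tfrac{1}{2} k (E - U(\omega))^2} when
#' \eqn{U(\omega) < E}, and 0 otherwise.
#'
#' @param E Threshold energy in kcal/mol.
#' @param k Force constant in 1/(kcal/mol), non-negative.
#' @return An object of class \code{boost_spec}.
#' @export
boost_spec <- function(E, k) {
  stopifnot(length(E) == 1, length(k) == 1)
  if (!is.finite(k) || k < 0) stop("'k' must be finite and >= 0")
  if (!is.finite(E)) stop("'E' must be finite")
  structure(list(E = E, k = k), class = "boost_spec")
}

#' Torsion potential specification
#'
#' A cosine-series torsion potential (one or more \code{\link{torsion_term}}s),
#' an optional harmonic \code{\link{boost_spec}}, and a temperature. This is
#' the ground truth object for synthetic boosted dihedral trajectories.
#'
#' @param terms A list of \code{torsion_term} objects (at least one), or a
#'   single \code{torsion_term}.
#' @param boost A \code{boost_spec}, or \code{NULL} for an unboosted potential.
#' @param temperature Temperature in Kelvin (default 300).
#' @return An object of class \code{torsion_potential}.
#' @examples
#' sp <- torsion_potential(torsion_term(2, 15, 180))
#' evaluate_potential(sp, c(0, 90, 180))
#' @export
torsion_potential <- function(terms, boost = NULL, temperature = 300) {
  if (inherits(terms, "torsion_term")) terms <- list(terms)
  if (!is.list(terms) || length(terms) == 0) {
    stop("'terms' must be a non-empty list of torsion_term objects")
  }
  if (!all(vapply(terms, inherits, logical(1), "torsion_term"))) {
    stop("every element of 'terms' must be a torsion_term")
  }
  if (!is.null(boost) && !inherits(boost, "boost_spec")) {
    stop("'boost' must be a boost_spec or NULL")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("'temperature' must be > 0")
  }
  structure(list(terms = terms, boost = boost, temperature = temperature),
            class = "torsion_potential")
}

#' @export
print.torsion_potential <- function(x, ...) {
  cat("Torsion potential:", length(x$terms), "term(s), T =",
      x$temperature, "K\n")
  for (tm in x$terms) {
    cat(sprintf("  n = %d, V = %g kcal/mol, gamma = %g deg\n",
                tm$n, tm$V, tm$gamma))
  }
  if (!is.null(x$boost)) {
    cat(sprintf("  boost: E = %g kcal/mol, k = %g 1/(kcal/mol)\n",
                x$boost$E, x$boost$k))
  }
  invisible(x)
}

#' Evaluate a torsion potential
#'
#' \eqn{U(\omega) = \sum_n (V_n/2)(1 + \cos(n\omega - \gamma_n))}, periodic
#' with period 360 degrees. Input angles may be any real; they are wrapped
#' internally.
#'
#' @param spec A \code{\link{torsion_potential}}.
#' @param omega Dihedral angles in degrees (vectorized).
#' @return Potential energy in kcal/mol, same length as \code{omega}.
#' @export
evaluate_potential <- function(spec, omega) {
  stopifnot(inherits(spec, "torsion_potential"))
  if (any(!is.finite(omega))) stop("'omega' must be finite")
  u <- numeric(length(omega))
  for (tm in spec$terms) {
    u <- u + (tm$V / 2) * (1 + cos((tm$n * omega - tm$gamma) * pi / 180))
  }
  u
}

#' Evaluate the harmonic boost energy
#'
#' \eqn{\Delta V(\omega) = \tfrac{1}{2} k (E - U(\omega))^2} where
#' \eqn{U(\omega) < E}, else 0. Returns zeros when the spec carries no boost.
#'
#' @inheritParams evaluate_potential
#' @return Boost energy in kcal/mol, same length as \code{omega}.
#' @export
boost_energy <- function(spec, omega) {
  u <- evaluate_potential(spec, omega)
  if (is.null(spec$boost)) return(numeric(length(u)))
  dv <- numeric(length(u))
  below <- u < spec$boost$E
  dv[below] <- 0.5 * spec$boost$k * (spec$boost$E - u[below])^2
  dv
}

#' Peptide-bond torsion presets
#'
#' The pure 2-fold cosine term that sets the cis/trans isomerization barrier
#' of the peptide bond (phase 180 degrees so that both planar states are
#' minima and the barrier sits at \eqn{\pm 90} degrees). The default force
#' field barrier is 20 kcal/mol; the lowered preset uses 15 kcal/mol to speed
#' isomerization sampling.
#'
#' @param which Either \code{"default"} (V2 = 20 kcal/mol) or
#'   \code{"lowered"} (V2 = 15 kcal/mol).
#' @param boost Optional \code{\link{boost_spec}} to attach.
#' @param temperature Temperature in Kelvin.
#' @return A \code{\link{torsion_potential}} with a single 2-fold term.
#' @export
peptide_torsion_preset <- function(which = c("lowered", "default"),
                                   boost = NULL, temperature = 300) {
  which <- match.arg(which)
  V2 <- switch(which, default = 20, lowered = 15)
  torsion_potential(torsion_term(2, V2, 180), boost = boost,
                    temperature = temperature)
}

#' Barrier height of a torsion potential
#'
#' Global maximum minus global minimum of \eqn{U(\omega)} over the full
#' dihedral circle, located numerically on a fine grid with local refinement.
#'
#' @inheritParams evaluate_potential
#' @param grid_deg Initial grid spacing in degrees.
#' @return Barrier height in kcal/mol.
#' @export
potential_barrier <- function(spec, grid_deg = 0.1) {
  om <- seq(-180 + grid_deg, 180, by = grid_deg)
  u <- evaluate_potential(spec, om)
  f <- function(w) evaluate_potential(spec, w)
  c_max <- om[which.max(u)]
  c_min <- om[which.min(u)]
  umax <- stats::optimize(f, interval = c_max + c(-1, 1) * grid_deg,
                          maximum = TRUE)$objective
  umin <- stats::optimize(f, interval = c_min + c(-1, 1) * grid_deg)$objective
  max(umax, max(u)) - min(umin, min(u))
}

#' Analytic Boltzmann probability of an angular interval
#'
#' Equilibrium probability \eqn{\int_{range} e^{-U/k_BT} d\omega /
#' \int_{circle} e^{-U/k_BT} d\omega} by composite trapezoid quadrature,
#' refined by grid doubling until successive estimates differ by less than
#' \code{tol}. Serves as the ground-truth oracle for sampling and reweighting
#' recovery checks.
#'
#' @inheritParams evaluate_potential
#' @param lo,hi Interval endpoints in degrees, interpreted on the circle:
#'   if \code{hi < lo} after wrapping, the interval wraps through 180/-180.
#' @param tol Refinement tolerance on the probability (default 1e-6).
#' @return A probability in [0, 1].
#' @examples
#' sp <- torsion_potential(list(torsion_term(2, 15, 180), torsion_term(1, 2, 0)))
#' analytic_state_probability(sp, -90, 50)   # cis occupancy
#' @export
analytic_state_probability <- function(spec, lo, hi, tol = 1e-6) {
  stopifnot(inherits(spec, "torsion_potential"))
  kT <- kB * spec$temperature
  lo <- wrap_angle(lo); hi <- wrap_angle(hi)
  if (isTRUE(all.equal(lo, hi))) return(0)
  # reduce a wrapped interval to segments on (-180, 180]
  segs <- if (hi > lo) list(c(lo, hi)) else list(c(lo, 180), c(-180, hi))
  trap <- function(a, b, n) {
    x <- seq(a, b, length.out = n + 1)
    f <- exp(-evaluate_potential(spec, x) / kT)
    (b - a) * (sum(f) - (f[1] + f[n + 1]) / 2) / n
  }
  integ <- function(a, b) {
    n <- 256
    est <- trap(a, b, n)
    repeat {
      n <- n * 2
      est2 <- trap(a, b, n)
      if (abs(est2 - est) < tol * 360 || n >= 2^20) return(est2)
      est <- est2
    }
  }
  num <- sum(vapply(segs, function(s) integ(s[1], s[2]), numeric(1)))
  den <- integ(-180, 180)
  p <- num / den
  min(max(p, 0), 1)
}

#' Calibrate a harmonic boost for a target boost level
#'
#' Chooses boost parameters the way a practitioner tunes acceleration: the
#' threshold is set to the potential's maximum over a fine grid (boost applies
#' everywhere below the barrier top) and the force constant is solved so the
#' mean of \eqn{\beta \Delta V} over the *biased* equilibrium ensemble
#' \eqn{\propto e^{-(U + \Delta V)/k_BT}} equals \code{target_mean_beta_dv}.
#'
#' @inheritParams evaluate_potential
#' @param target_mean_beta_dv Target dimensionless mean boost (default 1).
#' @return A \code{\link{torsion_potential}} equal to \code{spec} with the
#'   calibrated boost attached.
#' @export
calibrate_boost <- function(spec, target_mean_beta_dv = 1) {
  stopifnot(inherits(spec, "torsion_potential"),
            target_mean_beta_dv > 0)
  kT <- kB * spec$temperature
  om <- seq(-179.99, 180, by = 0.01)
  u <- evaluate_potential(spec, om)
  E <- max(u)
  mean_beta_dv <- function(k) {
    dv <- 0.5 * k * (E - u)^2
    w <- exp(-(u + dv - min(u + dv)) / kT)
    sum(w * dv / kT) / sum(w)
  }
  # mean beta*dV rises with k while the wells dominate, then falls once the
  # boost inverts the landscape; calibrate on the ascending (gentle) branch
  peak <- stats::optimize(function(logk) mean_beta_dv(exp(logk)),
                          interval = log(c(1e-8, 1e4)), maximum = TRUE)
  if (peak$objective < target_mean_beta_dv) {
    stop(sprintf(
      "target mean beta*deltaV %.3g unreachable (maximum %.3g)",
      target_mean_beta_dv, peak$objective))
  }
  f <- function(logk) mean_beta_dv(exp(logk)) - target_mean_beta_dv
  sol <- stats::uniroot(f, lower = log(1e-8), upper = peak$maximum,
                        tol = 1e-10)
  torsion_potential(spec$terms, boost = boost_spec(E, exp(sol$root)),
                    temperature = spec$temperature)
}
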