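# Omega-state classification, cis percentages, flipping frequencies,
# histograms, and the joint (n_cis x observable) distribution.

#' Default cis/trans omega ranges
#'
#' The empirically motivated state definitions on the wrapped circle:
#' cis = [-90, +50) and trans = [+100, +240) (equivalently
#' [+100, +180] plus (-180, -120) after wrapping), leaving the barrier
#' regions unassigned. Intervals are half-open at the upper edge for
#' deterministic boundary handling.
#' @format A list with elements \code{cis} and \code{trans}, each
#'   \code{c(lo, hi)} in degrees (\code{hi} may exceed 180 to denote a
#'   wrapped interval).
#' @export
omega_state_ranges <- list(cis = c(-90, 50), trans = c(100, 240))

in_circular_range <- function(w, range) {
  lo <- range[1]; hi <- range[2]
  if (hi <= 180) return(w >= lo & w < hi)
  # wrapped interval, e.g. 100..240 -> [100,180] U (-180,-120)
  w >= lo | w < wrap_angle(hi)
}

#' Classify a peptide-bond dihedral as cis, trans or unassigned
#'
#' Wraps the angle into (-180, 180] and assigns the isomeric state by the
#' range definitions in \code{\link{omega_state_ranges}}. Values in the
#' barrier gaps are \code{"unassigned"}. Classification is invariant to
#' adding multiples of 360 degrees.
#'
#' @param omega Angles in degrees (vectorized; any real).
#' @param ranges State ranges, defaulting to \code{omega_state_ranges}.
#' @return Character vector in \code{c("cis", "trans", "unassigned")}.
#' @examples
#' classify_omega(c(0, 180, -150, 75))
#' @export
classify_omega <- function(omega, ranges = omega_state_ranges) {
  if (any(!is.finite(omega))) stop("'omega' must be finite")
  w <- wrap_angle(omega)
  out <- rep("unassigned", length(w))
  out[in_circular_range(w, ranges$cis)] <- "cis"
  out[in_circular_range(w, ranges$trans)] <- "trans"
  out
}

#' Per-frame, per-site isomeric state matrix
#'
#' @param traj A \code{\link{dihedral_trajectory}}.
#' @param ranges State ranges, see \code{\link{classify_omega}}.
#' @return Character matrix (frames x sites) of states.
#' @export
isomer_states <- function(traj, ranges = omega_state_ranges) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  st <- apply(traj$omega, 2, classify_omega, ranges = ranges)
  matrix(st, nrow = n_frames(traj), ncol = n_sites(traj),
         dimnames = list(NULL, site_names(traj)))
}

#' Reweighted cis percentage per site
#'
#' Percentage of (weighted) time each site spends in cis among the assigned
#' frames: \eqn{100 \sum_{cis} w / \sum_{assigned} w}. Unassigned
#' barrier-region frames are excluded, so cis% and trans% sum to 100.
#'
#' @param states Character matrix from \code{\link{isomer_states}} (a vector
#'   is treated as one site).
#' @param weights A \code{frame_weights} object, or \code{NULL} for uniform.
#' @return Named numeric vector of per-site cis percentages.
#' @export
cis_percentage <- function(states, weights = NULL) {
  if (is.vector(states)) states <- matrix(states, ncol = 1)
  weights <- as_weights(weights, nrow(states))
  apply(states, 2, function(s) {
    assigned <- s != "unassigned"
    denom <- sum(weights$w[assigned])
    if (denom == 0) stop("site has no assigned frames")
    100 * sum(weights$w[assigned & s == "cis"]) / denom
  })
}

#' Cis/trans flipping frequency per site
#'
#' Counts cis/trans transitions between consecutive *assigned* frames:
#' unassigned barrier-region frames are bridged, so a crossing recorded as
#' cis, unassigned, trans counts once. The count is divided by the total
#' simulated span \eqn{(n_{frames}-1)\,\Delta t}. On synthetic Monte-Carlo
#' data this is a per-retained-frame event rate, not physical kinetics.
#'
#' @param states State matrix or vector (see \code{\link{cis_percentage}}).
#' @param dt_ps Frame interval in picoseconds.
#' @return Named numeric vector of flips per nanosecond.
#' @export
flip_frequency <- function(states, dt_ps) {
  if (is.vector(states)) states <- matrix(states, ncol = 1)
  nf <- nrow(states)
  if (nf < 2) stop("need at least 2 frames")
  span_ns <- (nf - 1) * dt_ps / 1000
  if (span_ns <= 0) stop("zero time span")
  apply(states, 2, function(s) {
    s <- s[s != "unassigned"]
    if (length(s) < 2) return(0)
    sum(s[-1] != s[-length(s)]) / span_ns
  })
}

#' Weighted circular histogram of omega
#'
#' Density-normalized weighted histogram over (-180, 180], in units of
#' probability per degree (integrates to 1 over the circle).
#'
#' @param omega Angle series in degrees, or a
#'   \code{\link{dihedral_trajectory}}.
#' @param weights A \code{frame_weights} object or \code{NULL}.
#' @param bins Number of equal bins or a breaks vector.
#' @param site Site selector when a trajectory is given.
#' @return Data frame with \code{bin_center_deg}, \code{density},
#'   \code{n_frames}.
#' @export
omega_histogram <- function(omega, weights = NULL, bins = 60, site = 1) {
  if (inherits(omega, "dihedral_trajectory")) omega <- omega$omega[, site]
  weights <- as_weights(weights, length(omega))
  b <- omega_bins(bins)
  idx <- bin_index(omega, b$breaks)
  nb <- length(b$mid)
  wsum <- vapply(seq_len(nb), function(j) sum(weights$w[idx == j]),
                 numeric(1))
  data.frame(bin_center_deg = b$mid, density = wsum / b$width,
             n_frames = tabulate(idx, nb))
}

#' Joint distribution of cis count and a scalar observable
#'
#' Reweighted two-dimensional probability table over (number of sites in
#' cis) x (binned observable, e.g. end-to-end distance in Angstrom). Cells
#' sum to one; marginalizing over the observable recovers the cis-count
#' distribution, marginalizing over the count recovers the observable's
#' weighted histogram.
#'
#' @param states State matrix from \code{\link{isomer_states}}.
#' @param observable Per-frame scalar series.
#' @param weights A \code{frame_weights} object or \code{NULL}.
#' @param breaks Observable bin breaks (default 30 equal bins over range).
#' @return Matrix of class \code{joint_distribution} with rows \code{n_cis =
#'   0..S} and observable-bin columns; attribute \code{breaks}.
#' @export
joint_distribution <- function(states, observable, weights = NULL,
                               breaks = 30) {
  if (is.vector(states)) states <- matrix(states, ncol = 1)
  nf <- nrow(states)
  if (length(observable) != nf) {
    stop("observable length does not match frames")
  }
  weights <- as_weights(weights, nf)
  ncis <- rowSums(states == "cis")
  S <- ncol(states)
  if (length(breaks) == 1) {
    rng <- range(observable)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = breaks + 1)
  }
  ob <- findInterval(observable, breaks, left.open = FALSE,
                     rightmost.closed = TRUE)
  ob[ob < 1 | ob > length(breaks) - 1] <- NA
  nb <- length(breaks) - 1
  m <- matrix(0, nrow = S + 1, ncol = nb,
              dimnames = list(n_cis = 0:S, bin = seq_len(nb)))
  keep <- !is.na(ob)
  for (i in which(keep)) m[ncis[i] + 1, ob[i]] <- m[ncis[i] + 1, ob[i]] +
      weights$w[i]
  m <- m / sum(m)
  structure(m, breaks = breaks, class = c("joint_distribution", "matrix"))
}

#' Centered running average
#'
#' Moving mean with a centered window that shrinks symmetrically at the
#' series edges; used to monitor convergence of slow structural observables.
#'
#' @param x Numeric series.
#' @param window Window length (>= 1; effective width 2*floor(window/2)+1).
#' @return Smoothed series of the same length.
#' @export
running_average <- function(x, window) {
  n <- length(x)
  if (window < 1) stop("'window' must be >= 1")
  if (window > n) stop("'window' exceeds the series length")
  h <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
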