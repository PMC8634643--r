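# Recovery of unbiased averages and PMFs from boosted trajectories:
# exponential (exact), Maclaurin-series and second-order cumulant estimators,
# plus the anharmonicity diagnostic that qualifies the cumulant route.

new_frame_weights <- function(w, method, beta) {
  structure(list(w = w, method = method, beta = beta),
            class = "frame_weights")
}

#' @export
print.frame_weights <- function(x, ...) {
  cat(sprintf("Frame weights (%s): %d frames, ESS = %.0f\n",
              x$method, length(x$w), 1 / sum(x$w^2)))
  invisible(x)
}

#' Exact exponential reweighting factors
#'
#' Per-frame weights \eqn{w_j \propto e^{\beta \Delta V_j}}, normalized to
#' sum to one. This is the exact estimator of the unbiased ensemble average
#' from a boosted run; the max is subtracted before exponentiation to guard
#' against overflow.
#'
#' @param deltaV Per-frame boost energies in kcal/mol (>= 0, finite), or a
#'   \code{\link{dihedral_trajectory}}.
#' @param temperature Temperature in Kelvin (taken from the trajectory if one
#'   is supplied).
#' @return A \code{frame_weights} object (fields \code{w}, \code{method},
#'   \code{beta}).
#' @export
exact_weights <- function(deltaV, temperature = 300) {
  if (inherits(deltaV, "dihedral_trajectory")) {
    temperature <- deltaV$temperature
    deltaV <- deltaV$deltaV
  }
  check_deltaV(deltaV)
  beta <- 1 / (kB * temperature)
  x <- beta * deltaV
  w <- exp(x - max(x))
  new_frame_weights(w / sum(w), "exact", beta)
}

#' Maclaurin-series reweighting factors
#'
#' Per-frame weights from the truncated Taylor expansion of the exponential,
#' \eqn{w_j \propto \sum_{k=0}^{K} (\beta \Delta V_j)^k / k!}, normalized.
#' The 10th order is the conventional choice; as the order grows the weights
#' converge to \code{\link{exact_weights}}. The truncation damps the largest
#' boosts, which is why PMFs built from these weights tend to underestimate
#' free-energy barrier heights while leaving the minima essentially intact.
#'
#' @inheritParams exact_weights
#' @param order Truncation order K (>= 0; default 10).
#' @return A \code{frame_weights} object with method \code{"maclaurin-K"}.
#' @export
maclaurin_weights <- function(deltaV, temperature = 300, order = 10) {
  if (inherits(deltaV, "dihedral_trajectory")) {
    temperature <- deltaV$temperature
    deltaV <- deltaV$deltaV
  }
  check_deltaV(deltaV)
  if (order < 0) stop("'order' must be >= 0")
  beta <- 1 / (kB * temperature)
  x <- beta * deltaV
  w <- rep(1, length(x))
  term <- rep(1, length(x))
  for (k in seq_len(order)) {
    term <- term * x / k
    w <- w + term
  }
  new_frame_weights(w / sum(w), paste0("maclaurin-", order), beta)
}

check_deltaV <- function(deltaV) {
  if (length(deltaV) == 0) stop("empty deltaV series")
  if (any(!is.finite(deltaV))) stop("'deltaV' must be finite")
  if (any(deltaV < 0)) stop("'deltaV' must be >= 0")
  invisible(TRUE)
}

#' Uniform weights
#'
#' Convenience constructor for unweighted (unboosted) data.
#' @param n Number of frames.
#' @param temperature Temperature in Kelvin.
#' @return A \code{frame_weights} object.
#' @export
uniform_weights <- function(n, temperature = 300) {
  new_frame_weights(rep(1 / n, n), "uniform", 1 / (kB * temperature))
}

as_weights <- function(weights, n, temperature = 300) {
  if (is.null(weights)) return(uniform_weights(n, temperature))
  stopifnot(inherits(weights, "frame_weights"))
  if (length(weights$w) != n) stop("weights length does not match frames")
  weights
}

#' Reweighted ensemble average
#'
#' \eqn{\sum_i w_i x_i} for normalized frame weights. With an indicator
#' observable this is the reweighted state probability.
#'
#' @param x Observable series (numeric or logical).
#' @param weights A \code{frame_weights} object.
#' @return A scalar.
#' @export
reweighted_mean <- function(x, weights) {
  stopifnot(inherits(weights, "frame_weights"))
  if (length(x) != length(weights$w)) {
    stop("observable and weights have different lengths")
  }
  sum(weights$w * as.numeric(x))
}

#' Block-bootstrap standard error of a reweighted mean
#'
#' Splits the frame series into contiguous blocks, resamples blocks with
#' replacement, and recomputes the reweighted mean on each resample
#' (re-deriving weights from the resampled boost energies so weight
#' normalization is honoured). Contiguous blocks absorb the autocorrelation
#' of the sampler.
#'
#' @param x Observable series.
#' @param deltaV Per-frame boost energies.
#' @param temperature Temperature in Kelvin.
#' @param method Weighting estimator: \code{"maclaurin"} or \code{"exact"}.
#' @param order Maclaurin order (ignored for exact).
#' @param n_blocks Number of contiguous blocks (default 20).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Optional seed for the resampling.
#' @return List with \code{mean}, \code{se}, \code{n_blocks}, \code{n_boot}.
#' @export
block_bootstrap_se <- function(x, deltaV, temperature = 300,
                               method = c("maclaurin", "exact"), order = 10,
                               n_blocks = 20, n_boot = 200, seed = NULL) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(deltaV) == n, n_blocks >= 2, n >= n_blocks)
  if (!is.null(seed)) set.seed(as.integer(seed))
  wfun <- function(dv) {
    if (method == "exact") exact_weights(dv, temperature)
    else maclaurin_weights(dv, temperature, order)
  }
  blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  est <- reweighted_mean(x, wfun(deltaV))
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- unlist(blocks[sample.int(n_blocks, n_blocks, replace = TRUE)],
                  use.names = FALSE)
    reweighted_mean(x[idx], wfun(deltaV[idx]))
  }, numeric(1))
  list(mean = est, se = stats::sd(boots), n_blocks = n_blocks,
       n_boot = n_boot)
}

# shared binning over the dihedral circle (-180, 180]
omega_bins <- function(bins) {
  if (length(bins) == 1) {
    breaks <- seq(-180, 180, length.out = bins + 1)
  } else {
    breaks <- bins
  }
  if (length(breaks) < 2) stop("need at least one bin")
  list(breaks = breaks, mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
       width = diff(breaks))
}

bin_index <- function(omega, breaks) {
  # half-open (lo, hi] bins so that +180 lands in the last bin
  findInterval(wrap_angle(omega), breaks, left.open = TRUE,
               rightmost.closed = FALSE, all.inside = FALSE)
}

new_pmf <- function(mid, width, f, n, wsum, estimator) {
  structure(list(bin_mid = mid, bin_width = width, f = f, n = n,
                 wsum = wsum, estimator = estimator),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF (%s): %d bins, %d empty, barrier = %.3f kcal/mol\n",
              x$estimator, length(x$f), sum(is.na(x$f)),
              pmf_barrier(x)))
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(bin_center_deg = x$bin_mid,
             free_energy_kcal_mol = x$f,
             n_frames = x$n, weight_sum = x$wsum)
}

#' Barrier height of a PMF profile
#'
#' Maximum free energy over non-empty bins; with the min-shift contract the
#' profile minimum is zero, so this is the apparent barrier.
#' @param pmf A \code{pmf_profile}.
#' @return Barrier in kcal/mol.
#' @export
pmf_barrier <- function(pmf) max(pmf$f, na.rm = TRUE)

#' PMF by second-order cumulant reweighting
#'
#' Free energy per angular bin
#' \deqn{F_j = -k_BT \ln p^{biased}_j - [\langle\Delta V\rangle_j +
#'   \tfrac{\beta}{2}\sigma^2_{\Delta V,j}] + C,}
#' the exponential average approximated through its first two cumulants
#' computed over the frames that fall in bin \eqn{j}; \eqn{C} is chosen so
#' the minimum over non-empty bins is exactly zero. Accurate when the boost
#' energy is near-Gaussian within each bin (see
#' \code{\link{anharmonicity}}).
#'
#' @param omega Angle series in degrees, or a
#'   \code{\link{dihedral_trajectory}} (its first site is used unless
#'   \code{site} is given).
#' @param deltaV Boost energy series (ignored when a trajectory is given).
#' @param temperature Kelvin.
#' @param bins Number of equal bins over (-180, 180] (default 60, i.e. 6
#'   degrees), or an explicit breaks vector.
#' @param site Site name or index when \code{omega} is a trajectory.
#' @return A \code{pmf_profile}; empty bins carry \code{NA} and never
#'   participate in the min-shift.
#' @export
pmf_cumulant2 <- function(omega, deltaV = NULL, temperature = 300,
                          bins = 60, site = 1) {
  if (inherits(omega, "dihedral_trajectory")) {
    temperature <- omega$temperature
    deltaV <- omega$deltaV
    omega <- omega$omega[, site]
  }
  stopifnot(length(omega) == length(deltaV))
  kT <- kB * temperature
  beta <- 1 / kT
  b <- omega_bins(bins)
  idx <- bin_index(omega, b$breaks)
  nb <- length(b$mid)
  cnt <- tabulate(idx, nb)
  if (all(cnt == 0)) stop("all bins are empty")
  f <- rep(NA_real_, nb)
  for (j in which(cnt > 0)) {
    dvj <- deltaV[idx == j]
    corr <- mean(dvj) + if (length(dvj) > 1) (beta / 2) * stats::var(dvj) else 0
    f[j] <- -kT * log(cnt[j] / sum(cnt)) - corr
  }
  f <- f - min(f, na.rm = TRUE)
  new_pmf(b$mid, b$width, f, cnt, cnt / sum(cnt), "cumulant2")
}

#' PMF from per-frame weights
#'
#' \eqn{F_j = -k_BT \ln \sum_{i \in bin j} w_i + C}, min-shifted over
#' non-empty bins. Used with Maclaurin (or exact) weights.
#'
#' @inheritParams pmf_cumulant2
#' @param weights A \code{frame_weights} object (e.g. from
#'   \code{\link{maclaurin_weights}}).
#' @return A \code{pmf_profile}.
#' @export
pmf_from_weights <- function(omega, weights, temperature = 300, bins = 60,
                             site = 1) {
  if (inherits(omega, "dihedral_trajectory")) {
    temperature <- omega$temperature
    omega <- omega$omega[, site]
  }
  weights <- as_weights(weights, length(omega), temperature)
  kT <- kB * temperature
  b <- omega_bins(bins)
  idx <- bin_index(omega, b$breaks)
  nb <- length(b$mid)
  cnt <- tabulate(idx, nb)
  if (all(cnt == 0)) stop("all bins are empty")
  wsum <- vapply(seq_len(nb), function(j) sum(weights$w[idx == j]),
                 numeric(1))
  f <- ifelse(cnt > 0 & wsum > 0, -kT * log(wsum), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  new_pmf(b$mid, b$width, f, cnt, wsum,
          paste0("weights-", weights$method))
}

# Miller-Madow corrected histogram differential entropy; h from the
# Freedman-Diaconis rule on the supplied values
hist_entropy <- function(x) {
  n <- length(x)
  h <- 2 * stats::IQR(x) / n^(1 / 3)
  if (!is.finite(h) || h <= 0) return(NA_real_)
  edges <- seq(min(x) - h / 2, max(x) + h, by = h)
  p <- tabulate(findInterval(x, edges), length(edges)) / n
  p <- p[p > 0]
  -sum(p * log(p)) + log(h) + (length(p) - 1) / (2 * n)
}

#' Boost-energy anharmonicity along the dihedral
#'
#' For each angular bin, the deviation of the boost-energy distribution from
#' a Gaussian, measured as the entropy deficit
#' \eqn{\gamma = S_{gauss} - S_{emp}}: \eqn{S_{gauss} = \tfrac12
#' \ln(2\pi e \sigma^2)} is the maximum-entropy reference at the bin's
#' variance and \eqn{S_{emp}} is a histogram estimate of the differential
#' entropy (Freedman-Diaconis width, Miller-Madow bias correction). The
#' population-weighted average is compared (in absolute value, since the
#' finite-sample estimate can dip below zero) against a cutoff of
#' \eqn{10^{-3}}: small values certify that second-order cumulant
#' reweighting is reliable.
#'
#' @inheritParams pmf_cumulant2
#' @param cutoff Pass threshold on \code{|average gamma|} (default 1e-3).
#' @return An object of class \code{anharmonicity_report}: per-bin table
#'   (\code{bin_center_deg}, \code{gamma}, \code{n_frames}),
#'   \code{average} (population weighted) and \code{pass}.
#' @export
anharmonicity <- function(omega, deltaV = NULL, bins = 60, cutoff = 1e-3,
                          site = 1) {
  if (inherits(omega, "dihedral_trajectory")) {
    deltaV <- omega$deltaV
    omega <- omega$omega[, site]
  }
  stopifnot(length(omega) == length(deltaV))
  b <- omega_bins(bins)
  idx <- bin_index(omega, b$breaks)
  nb <- length(b$mid)
  cnt <- tabulate(idx, nb)
  if (!any(cnt >= 2)) stop("need at least one bin with >= 2 frames")
  gamma <- rep(NA_real_, nb)
  for (j in which(cnt >= 2)) {
    dvj <- deltaV[idx == j]
    s2 <- stats::var(dvj)
    if (s2 == 0) { gamma[j] <- 0; next }
    s_emp <- hist_entropy(dvj)
    gamma[j] <- if (is.na(s_emp)) 0 else 0.5 * log(2 * pi * exp(1) * s2) - s_emp
  }
  ok <- !is.na(gamma)
  avg <- sum(gamma[ok] * cnt[ok]) / sum(cnt[ok])
  structure(list(table = data.frame(bin_center_deg = b$mid, gamma = gamma,
                                    n_frames = cnt),
                 average = avg, cutoff = cutoff, pass = abs(avg) < cutoff),
            class = "anharmonicity_report")
}

#' @export
print.anharmonicity_report <- function(x, ...) {
  cat(sprintf("Anharmonicity: average gamma = %.2e (cutoff %.0e) -> %s\n",
              x$average, x$cutoff, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Write a PMF profile to delimited text
#' @param pmf A \code{pmf_profile}.
#' @param path Output path.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
write_pmf <- function(pmf, path, sep = ",") {
  utils::write.table(as.data.frame(pmf), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
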