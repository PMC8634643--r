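# Independence analysis of multi-proline cis states: expected (product of
# marginals) versus observed (reweighted joint occupancy) for all site
# subsets, with across-replicate spread.

#' Expected joint cis percentage under independence
#'
#' If isomerization at different sites is uncorrelated, the fraction of time
#' a group of sites is simultaneously cis equals the product of the member
#' marginals: \eqn{100 \prod_{i \in subset} p_i}.
#'
#' @param marginals Per-site cis fractions in [0, 1] (named or positional).
#' @param subset Indices or names of the member sites (non-empty).
#' @return Expected joint cis percentage.
#' @export
expected_joint_cis <- function(marginals, subset) {
  if (length(subset) == 0) stop("'subset' must be non-empty")
  p <- marginals[subset]
  if (any(is.na(p))) stop("subset site absent from marginals")
  if (any(p < 0 | p > 1)) stop("marginals must be in [0, 1]")
  100 * prod(p)
}

#' Observed joint cis percentage
#'
#' Reweighted fraction of frames in which every subset site is
#' simultaneously cis, times 100, among the frames where every subset site
#' is assigned (cis or trans) — the same conditioning as the per-site
#' marginals, so a maximally correlated (locked) fixture reproduces its
#' marginal exactly.
#'
#' @param states State matrix from \code{\link{isomer_states}}.
#' @param weights A \code{frame_weights} object or \code{NULL}.
#' @param subset Column indices or names of the member sites.
#' @return Observed joint cis percentage.
#' @export
observed_joint_cis <- function(states, weights = NULL, subset) {
  if (is.vector(states)) states <- matrix(states, ncol = 1)
  if (is.character(subset) && !all(subset %in% colnames(states))) {
    stop("subset site absent from state matrix")
  }
  if (is.numeric(subset) && any(subset > ncol(states))) {
    stop("subset site absent from state matrix")
  }
  weights <- as_weights(weights, nrow(states))
  sub <- states[, subset, drop = FALSE]
  all_cis <- rowSums(sub == "cis") == length(subset)
  all_assigned <- rowSums(sub != "unassigned") == length(subset)
  denom <- sum(weights$w[all_assigned])
  if (denom == 0) stop("no frames with every subset site assigned")
  100 * sum(weights$w[all_cis]) / denom
}

#' Multi-proline cis correlation report
#'
#' For every subset of sites up to \code{max_size}, compares the observed
#' joint cis occupancy with the value expected under independence. Each
#' replicate is reweighted independently; replicates are then averaged
#' unweighted and their standard deviation (ddof = 1) reported. With a
#' single replicate the standard deviation is \code{NA}. No formal test is
#' attached: following the convention of reporting spread across independent
#' simulations, non-overlap of the error intervals is read descriptively.
#'
#' @param trajectories A \code{\link{dihedral_trajectory}} or a list of them
#'   (one per replicate), all with the same sites.
#' @param max_size Largest subset size (default: all sites).
#' @param min_size Smallest subset size (default 2).
#' @param method Reweighting estimator passed to the weight constructors:
#'   \code{"maclaurin"} or \code{"exact"}.
#' @param order Maclaurin order.
#' @param ranges State ranges for \code{\link{classify_omega}}.
#' @return Data frame of class \code{correlation_report}: \code{subset}
#'   (site names joined by \code{"+"}), \code{size}, \code{expected_pct},
#'   \code{observed_pct_mean}, \code{observed_pct_sd}, \code{n_replicates}.
#' @export
correlation_report <- function(trajectories, max_size = NULL, min_size = 2,
                               method = c("maclaurin", "exact"), order = 10,
                               ranges = omega_state_ranges) {
  method <- match.arg(method)
  if (inherits(trajectories, "dihedral_trajectory")) {
    trajectories <- list(trajectories)
  }
  stopifnot(length(trajectories) >= 1)
  sn <- site_names(trajectories[[1]])
  S <- length(sn)
  if (is.null(max_size)) max_size <- S
  max_size <- min(max_size, S)
  per_rep <- lapply(trajectories, function(tr) {
    w <- if (method == "exact") exact_weights(tr) else {
      maclaurin_weights(tr, order = order)
    }
    st <- isomer_states(tr, ranges)
    marg <- cis_percentage(st, w) / 100
    list(states = st, w = w, marg = marg)
  })
  rows <- list()
  for (k in seq(min_size, max_size)) {
    for (cmb in utils::combn(S, k, simplify = FALSE)) {
      exp_r <- vapply(per_rep, function(r) expected_joint_cis(r$marg, cmb),
                      numeric(1))
      obs_r <- vapply(per_rep, function(r) {
        observed_joint_cis(r$states, r$w, cmb)
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        subset = paste(sn[cmb], collapse = "+"), size = k,
        expected_pct = mean(exp_r),
        observed_pct_mean = mean(obs_r),
        observed_pct_sd = if (length(obs_r) > 1) stats::sd(obs_r) else NA_real_,
        expected_pct_sd = if (length(exp_r) > 1) stats::sd(exp_r) else NA_real_,
        n_replicates = length(per_rep), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_report", "data.frame")
  out
}
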