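# Synthetic boosted trajectory generation: the stand-in for accelerated-MD
# production runs, with analytically known unbiased equilibria.

#' Sample a boosted dihedral trajectory
#'
#' Metropolis Monte Carlo on the boosted torsion surface
#' \eqn{U^*(\omega) = U(\omega) + \Delta V(\omega)}. Every retained frame
#' records the angle and the boost energy \eqn{\Delta V(\omega)}, exactly as
#' an accelerated-MD engine would, so the reweighting stage can recover the
#' unbiased ensemble. Proposals are symmetric uniform perturbations, so the
#' chain obeys detailed balance with respect to \eqn{e^{-U^*/k_BT}}.
#'
#' Only equilibrium populations are meaningful on this synthetic dynamics;
#' "time" is the retained-frame interval, not physical kinetics.
#'
#' @param spec A \code{\link{torsion_potential}} (with or without boost).
#' @param n_frames Number of frames to retain (>= 1).
#' @param seed Integer seed; required, for reproducibility.
#' @param proposal_width Half-width of the uniform proposal, degrees in
#'   (0, 180].
#' @param burn_in Discarded equilibration steps (default 1e4).
#' @param dt_ps Nominal frame interval in ps (default 0.1).
#' @param omega0 Starting angle in degrees (default 180, the trans state).
#' @param site Site label for the output column.
#' @param replicate Replicate label.
#' @return A \code{\link{dihedral_trajectory}} with one site.
#' @examples
#' sp <- torsion_potential(torsion_term(2, 4, 180))
#' tr <- sample_boosted_trajectory(sp, 1000, seed = 1)
#' @export
sample_boosted_trajectory <- function(spec, n_frames, seed,
                                      proposal_width = 30, burn_in = 1e4,
                                      dt_ps = 0.1, omega0 = 180,
                                      site = "site1", replicate = "r1") {
  stopifnot(inherits(spec, "torsion_potential"))
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("'seed' is required: synthetic trajectories must be reproducible")
  }
  if (n_frames < 1) stop("'n_frames' must be >= 1")
  if (proposal_width <= 0 || proposal_width > 180) {
    stop("'proposal_width' must be in (0, 180] degrees")
  }
  kT <- kB * spec$temperature
  n <- vapply(spec$terms, `[[`, numeric(1), "n")
  v <- vapply(spec$terms, `[[`, numeric(1), "V")
  g <- vapply(spec$terms, `[[`, numeric(1), "gamma")
  has_boost <- !is.null(spec$boost)
  set.seed(as.integer(seed))
  res <- metropolis_omega(n, v, g,
                          if (has_boost) spec$boost$E else 0,
                          if (has_boost) spec$boost$k else 0,
                          has_boost, kT, as.integer(n_frames),
                          as.integer(burn_in), proposal_width, omega0)
  om <- matrix(res$omega, ncol = 1, dimnames = list(NULL, site))
  dihedral_trajectory(om, dt_ps = dt_ps, deltaV = res$deltaV,
                      temperature = spec$temperature, replicate = replicate)
}

#' Generate a multi-site boosted trajectory
#'
#' Combines several single-site torsion models into one trajectory. With
#' \code{coupling = "independent"} each site runs its own Metropolis chain
#' under a distinct sub-seed (the null model in which isomerization events at
#' different prolines are uncorrelated); with \code{coupling = "locked"} all
#' sites share one angle series, the maximal-correlation fixture. The
#' per-frame boost energy is the sum over sites, each site's boost evaluated
#' from its own spec.
#'
#' @param specs List of \code{\link{torsion_potential}} objects, one per
#'   site (a single spec is recycled when \code{n_sites} is given).
#' @param coupling \code{"independent"} or \code{"locked"}.
#' @param n_frames Frames to retain.
#' @param seed Integer master seed; site sub-seeds are drawn from it.
#' @param site_names Optional site labels (default \code{site1, site2, ...}).
#' @param ... Passed on to \code{\link{sample_boosted_trajectory}}.
#' @return A \code{\link{dihedral_trajectory}} with one column per site.
#' @export
generate_multisite <- function(specs, coupling = c("independent", "locked"),
                               n_frames, seed, site_names = NULL, ...) {
  coupling <- match.arg(coupling)
  if (inherits(specs, "torsion_potential")) specs <- list(specs)
  ns <- length(specs)
  if (ns < 1) stop("need at least one site spec")
  if (is.null(site_names)) site_names <- paste0("site", seq_len(ns))
  set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, ns)
  if (coupling == "independent") {
    trs <- lapply(seq_len(ns), function(i) {
      sample_boosted_trajectory(specs[[i]], n_frames, seed = subseeds[i],
                                site = site_names[i], ...)
    })
    om <- do.call(cbind, lapply(trs, `[[`, "omega"))
    dv <- Reduce(`+`, lapply(trs, `[[`, "deltaV"))
    base <- trs[[1]]
  } else {
    base <- sample_boosted_trajectory(specs[[1]], n_frames,
                                      seed = subseeds[1],
                                      site = site_names[1], ...)
    om <- base$omega[, rep(1, ns), drop = FALSE]
    colnames(om) <- site_names
    dv <- Reduce(`+`, lapply(specs, function(sp) boost_energy(sp, om[, 1])))
  }
  dihedral_trajectory(om, dt_ps = base$dt_ps, deltaV = dv,
                      temperature = base$temperature,
                      replicate = base$replicate)
}

# canonical dihedral boxes for the two polyproline helices; the trans omega
# range +100..+240 is stored unwrapped and wrapped at draw time
ppii_box <- list(phi = c(-104.6, -46.6), psi = c(107.9, 165.9),
                 omega = c(100, 240))
ppi_box <- list(phi = c(-104.6, -46.6), psi = c(131, 189),
                omega = c(-90, 50))

#' Emulate backbone dihedrals with known secondary-structure labels
#'
#' Draws per-frame \eqn{(\phi, \psi, \omega)} triples uniformly inside the
#' canonical dihedral box of the requested polyproline class (PPII: left
#' handed all-trans helix; PPI: right-handed all-cis helix), or outside both
#' boxes for \code{"other"}. The construction guarantees the classifier
#' round-trips the labels exactly, giving a ground-truth fixture for
#' secondary-structure fraction estimates.
#'
#' @param labels Character vector of per-frame targets, each one of
#'   \code{"PPII"}, \code{"PPI"}, \code{"other"}.
#' @param seed Integer seed.
#' @return A data frame with columns \code{phi}, \code{psi}, \code{omega}
#'   (degrees, wrapped) and \code{label}.
#' @export
emulate_backbone <- function(labels, seed) {
  if (length(labels) == 0) stop("'labels' must be non-empty")
  bad <- setdiff(unique(labels), c("PPII", "PPI", "other"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  nf <- length(labels)
  phi <- psi <- omega <- numeric(nf)
  draw_box <- function(k, box) {
    list(phi = stats::runif(k, box$phi[1], box$phi[2]),
         psi = wrap_angle(stats::runif(k, box$psi[1], box$psi[2])),
         omega = wrap_angle(stats::runif(k, box$omega[1], box$omega[2])))
  }
  for (cls in c("PPII", "PPI")) {
    idx <- which(labels == cls)
    if (!length(idx)) next
    d <- draw_box(length(idx), if (cls == "PPII") ppii_box else ppi_box)
    phi[idx] <- d$phi; psi[idx] <- d$psi; omega[idx] <- d$omega
  }
  idx <- which(labels == "other")
  if (length(idx)) {
    todo <- idx
    while (length(todo)) {
      p <- stats::runif(length(todo), -180, 180)
      s <- stats::runif(length(todo), -180, 180)
      o <- stats::runif(length(todo), -180, 180)
      ok <- assign_ppii_ppi(p, s, o) == "other"
      phi[todo[ok]] <- p[ok]; psi[todo[ok]] <- s[ok]; omega[todo[ok]] <- o[ok]
      todo <- todo[!ok]
    }
  }
  data.frame(phi = phi, psi = psi, omega = omega, label = labels,
             stringsAsFactors = FALSE)
}
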