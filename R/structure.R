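# Polyproline secondary-structure assignment from backbone dihedrals and
# proline ring-pucker assignment from chi2.

#' Assign PPII/PPI helix labels from backbone dihedrals
#'
#' Per-frame, per-residue assignment against the canonical dihedral boxes:
#' \itemize{
#'   \item PPII (left-handed, all-trans): \eqn{\phi \in [-104.6, -46.6]},
#'     \eqn{\psi \in [107.9, 165.9]}, \eqn{\omega} in the trans range.
#'   \item PPI (right-handed, all-cis): \eqn{\phi \in [-104.6, -46.6]},
#'     \eqn{\psi \in [131, 189]} (wrapped, i.e. \eqn{[131, 180] \cup
#'     (-180, -171]}), \eqn{\omega} in the cis range.
#' }
#' The two classes cannot overlap because their \eqn{\omega} ranges are
#' disjoint. Everything else is \code{"other"}. Boxes are closed at the
#' printed bounds; the \eqn{\omega} ranges follow
#' \code{\link{classify_omega}}.
#'
#' @param phi,psi,omega Dihedral angles in degrees (vectorized, finite).
#' @return Character vector in \code{c("PPII", "PPI", "other")}.
#' @examples
#' assign_ppii_ppi(-75, 145, 180)  # PPII
#' assign_ppii_ppi(-75, 160, 0)    # PPI
#' @export
assign_ppii_ppi <- function(phi, psi, omega) {
  if (any(!is.finite(phi)) || any(!is.finite(psi)) ||
      any(!is.finite(omega))) stop("angles must be finite")
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  st <- classify_omega(omega)
  phi_ok <- phi >= -104.6 & phi <= -46.6
  ppii <- phi_ok & psi >= 107.9 & psi <= 165.9 & st == "trans"
  # psi 131..189 wraps past 180: [131, 180] or (-180, -171]
  ppi <- phi_ok & (psi >= 131 | psi <= wrap_angle(189)) & st == "cis"
  out <- rep("other", length(phi))
  out[ppii] <- "PPII"
  out[ppi] <- "PPI"
  out
}

#' Proline ring pucker from chi2
#'
#' Canonical cutoffs on the side-chain \eqn{\chi_2} dihedral
#' (C\eqn{\alpha}-C\eqn{\beta}-C\eqn{\gamma}-C\eqn{\delta}): up pucker for
#' \eqn{\chi_2 > +10} degrees, down pucker for \eqn{\chi_2 < -10}, planar in
#' between (inclusive).
#'
#' @param chi2 Angles in degrees (vectorized, finite).
#' @return Character vector in \code{c("up", "down", "planar")}.
#' @export
pucker_state <- function(chi2) {
  if (any(!is.finite(chi2))) stop("'chi2' must be finite")
  w <- wrap_angle(chi2)
  ifelse(w > 10, "up", ifelse(w < -10, "down", "planar"))
}

#' Reweighted secondary-structure fractions by residue
#'
#' Fraction of the (weighted) ensemble carrying each label at each residue,
#' plus the peptide average (mean over residues). With exact label ground
#' truth the fractions round-trip exactly; on an all-trans ensemble the PPI
#' fraction is zero because PPI requires a cis peptide bond.
#'
#' @param labels Character matrix (frames x residues) of labels from
#'   \code{\link{assign_ppii_ppi}}, or a vector for one residue.
#' @param weights A \code{frame_weights} object or \code{NULL} for uniform.
#' @return Data frame with one row per residue plus a \code{"peptide"}
#'   average row; columns \code{residue}, \code{PPII}, \code{PPI},
#'   \code{other}.
#' @export
ss_fraction_by_residue <- function(labels, weights = NULL) {
  if (is.vector(labels)) labels <- matrix(labels, ncol = 1)
  nf <- nrow(labels)
  weights <- as_weights(weights, nf)
  if (is.null(colnames(labels))) {
    colnames(labels) <- paste0("res", seq_len(ncol(labels)))
  }
  classes <- c("PPII", "PPI", "other")
  frac <- t(apply(labels, 2, function(l) {
    vapply(classes, function(cl) sum(weights$w[l == cl]), numeric(1))
  }))
  frac <- frac / rowSums(frac)
  out <- data.frame(residue = colnames(labels), frac, row.names = NULL,
                    check.names = FALSE)
  rbind(out, data.frame(residue = "peptide",
                        t(colMeans(frac)), check.names = FALSE))
}
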