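# Circular-dichroism bookkeeping: raw millidegrees to mean residue
# ellipticity, empirical PPII quantification from the 228 nm band,
# scale-factor fitting between calculated and measured spectra, and
# fraction-weighted combination of basis spectra.

#' CD spectrum container
#'
#' Wavelength grid (nm, strictly increasing, within 170-280 nm) versus mean
#' residue ellipticity (deg cm^2 dmol^-1), with a provenance tag.
#'
#' @param wavelength_nm Strictly increasing numeric vector.
#' @param mre Mean residue ellipticity values, same length.
#' @param provenance One of \code{"measured"}, \code{"calculated"},
#'   \code{"scaled"}.
#' @return An object of class \code{cd_spectrum} (a data frame).
#' @export
cd_spectrum <- function(wavelength_nm, mre,
                        provenance = c("measured", "calculated", "scaled")) {
  provenance <- match.arg(provenance)
  stopifnot(length(wavelength_nm) == length(mre), length(mre) >= 1)
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (min(wavelength_nm) < 170 || max(wavelength_nm) > 280) {
    stop("wavelength grid must lie within 170-280 nm")
  }
  structure(data.frame(wavelength_nm = wavelength_nm, mre = mre),
            provenance = provenance,
            class = c("cd_spectrum", "data.frame"))
}

#' Sample information for ellipticity conversion
#'
#' @param conc_M Molar peptide concentration (mol/L, > 0).
#' @param path_cm Cuvette path length in cm (> 0).
#' @param n_residues Number of residues (positive integer).
#' @return An object of class \code{sample_info}.
#' @export
sample_info <- function(conc_M, path_cm, n_residues) {
  stopifnot(conc_M > 0, path_cm > 0, n_residues > 0,
            n_residues == round(n_residues))
  structure(list(conc_M = conc_M, path_cm = path_cm,
                 n_residues = as.integer(n_residues)),
            class = "sample_info")
}

#' Convert raw ellipticity (millidegrees) to mean residue ellipticity
#'
#' \deqn{[\theta]_{MR} = \frac{100 \times \theta_{deg}}{c_{MR} \times l},
#'   \qquad c_{MR} = n \times c,}
#' with \eqn{\theta_{deg}} the signal in degrees (input millidegrees /
#' 1000), \eqn{c} the molar concentration, \eqn{l} the path length in cm and
#' \eqn{n} the residue count. Result in deg cm^2 dmol^-1.
#'
#' @param wavelength_nm Wavelength grid (nm).
#' @param ellipticity_mdeg Raw signal in millidegrees.
#' @param sample A \code{\link{sample_info}}.
#' @return A \code{\link{cd_spectrum}} tagged \code{"measured"}.
#' @export
millideg_to_mre <- function(wavelength_nm, ellipticity_mdeg, sample) {
  stopifnot(inherits(sample, "sample_info"))
  c_mr <- sample$n_residues * sample$conc_M
  mre <- 100 * (ellipticity_mdeg / 1000) / (c_mr * sample$path_cm)
  cd_spectrum(wavelength_nm, mre, "measured")
}

#' Inverse of \code{millideg_to_mre} for a single value series
#' @inheritParams millideg_to_mre
#' @param mre Mean residue ellipticity values.
#' @return Raw ellipticity in millidegrees.
#' @export
mre_to_millideg <- function(mre, sample) {
  stopifnot(inherits(sample, "sample_info"))
  c_mr <- sample$n_residues * sample$conc_M
  1000 * mre * (c_mr * sample$path_cm) / 100
}

#' PPII percentage from the 228 nm ellipticity
#'
#' Empirical calibration for short proline-rich peptides relating the mean
#' residue ellipticity of the positive band at 228 nm to the PPII helix
#' content: \deqn{\%PPII = (\theta_{228} + 6100) / 137.00,} with
#' \eqn{\theta_{228}} in deg cm^2 dmol^-1. The denominator is 137.00 per
#' 1000-scaled ellipticity unit; at \eqn{\theta_{228} = -6100} the content
#' is zero by construction.
#'
#' @param theta_228 Ellipticity at 228 nm, deg cm^2 dmol^-1 (vectorized).
#' @return PPII percentage.
#' @examples
#' ppii_from_ellipticity(-796)   # 38.7
#' ppii_from_ellipticity(-334)   # 42.1
#' @export
ppii_from_ellipticity <- function(theta_228) {
  if (any(!is.finite(theta_228))) stop("'theta_228' must be finite")
  (theta_228 + 6100) / 137.00
}

interp_common <- function(calculated, reference, range = NULL) {
  lo <- max(min(calculated$wavelength_nm), min(reference$wavelength_nm))
  hi <- min(max(calculated$wavelength_nm), max(reference$wavelength_nm))
  if (!is.null(range)) {
    lo <- max(lo, range[1]); hi <- min(hi, range[2])
  }
  if (hi <= lo) stop("spectra have no overlapping wavelength range")
  sub <- function(s) s[s$wavelength_nm >= lo & s$wavelength_nm <= hi, ]
  cs <- sub(calculated); rs <- sub(reference)
  # evaluate the coarser spectrum on the finer grid by linear interpolation
  if (nrow(cs) >= nrow(rs)) {
    grid <- cs$wavelength_nm
    list(calc = cs$mre,
         ref = stats::approx(reference$wavelength_nm, reference$mre,
                             xout = grid)$y)
  } else {
    grid <- rs$wavelength_nm
    list(calc = stats::approx(calculated$wavelength_nm, calculated$mre,
                              xout = grid)$y,
         ref = rs$mre)
  }
}

#' Least-squares scale factor between two spectra
#'
#' The scalar \eqn{s} minimizing \eqn{\sum_\lambda (s\,calc(\lambda) -
#' ref(\lambda))^2} over the common wavelength range (closed form
#' \eqn{\sum calc \cdot ref / \sum calc^2}); the coarser grid is linearly
#' interpolated onto the finer one. Used to reconcile calculated spectra
#' with a measured one whose absolute scale carries concentration error.
#'
#' @param calculated,reference \code{\link{cd_spectrum}} objects.
#' @param range Optional \code{c(lo, hi)} wavelength sub-range (nm).
#' @return The scale factor (scalar).
#' @export
scale_factor <- function(calculated, reference, range = NULL) {
  g <- interp_common(calculated, reference, range)
  sum(g$calc * g$ref) / sum(g$calc^2)
}

#' Apply a scale factor to a spectrum
#' @param spectrum A \code{\link{cd_spectrum}}.
#' @param s Scale factor.
#' @return A \code{cd_spectrum} tagged \code{"scaled"}.
#' @export
apply_scale <- function(spectrum, s) {
  cd_spectrum(spectrum$wavelength_nm, spectrum$mre * s, "scaled")
}

#' Combine basis spectra by ensemble fractions
#'
#' Pointwise convex combination \eqn{\sum_c f_c \, basis_c(\lambda)} of
#' per-class basis spectra weighted by ensemble secondary-structure
#' fractions. Fractions must be non-negative and sum to one (within 1e-6)
#' and the class sets must match; only the linear-combination contract is
#' implemented here, basis-set derivation is external.
#'
#' @param fractions Named numeric vector of per-class fractions.
#' @param basis Named list of \code{\link{cd_spectrum}} objects on a common
#'   wavelength grid, or a long data frame with columns \code{class},
#'   \code{wavelength_nm}, \code{value}.
#' @return A \code{cd_spectrum} tagged \code{"calculated"}.
#' @export
combine_basis <- function(fractions, basis) {
  if (is.data.frame(basis)) {
    basis <- split(basis, basis$class)
    basis <- lapply(basis, function(d) {
      d <- d[order(d$wavelength_nm), ]
      cd_spectrum(d$wavelength_nm, d$value, "calculated")
    })
  }
  if (is.null(names(fractions)) || is.null(names(basis))) {
    stop("fractions and basis must be named by class")
  }
  if (!setequal(names(fractions), names(basis))) {
    stop("class sets of fractions and basis do not match")
  }
  if (any(fractions < 0)) stop("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  grid <- basis[[1]]$wavelength_nm
  for (b in basis) {
    if (!isTRUE(all.equal(b$wavelength_nm, grid))) {
      stop("basis spectra must share one wavelength grid")
    }
  }
  vals <- Reduce(`+`, lapply(names(fractions), function(cl) {
    fractions[[cl]] * basis[[cl]]$mre
  }))
  cd_spectrum(grid, vals, "calculated")
}

#' Read a two-column spectrum file
#'
#' Delimited text (comma or tab autodetected) with a header row
#' \code{wavelength_nm, value}; \code{#} comments ignored.
#' @param path File path.
#' @param provenance Provenance tag for the result.
#' @return A \code{\link{cd_spectrum}}.
#' @export
read_spectrum <- function(path, provenance = "measured") {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  cd_spectrum(df[[1]], df[[2]], provenance)
}

#' Write a spectrum to delimited text
#' @param spectrum A \code{\link{cd_spectrum}}.
#' @param path Output path.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spectrum, path, sep = ",") {
  utils::write.table(data.frame(wavelength_nm = spectrum$wavelength_nm,
                                value = spectrum$mre),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
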