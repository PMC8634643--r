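#!/usr/bin/env Rscript
# Stage 6: circular-dichroism bookkeeping. Builds two synthetic basis
# spectra (a PPII-like class with the characteristic ~228 nm positive band
# and a disordered class), combines them with the stage-4 ensemble
# fractions, fits a least-squares scale factor against a synthetic
# "measured" spectrum, and quantifies PPII content from the 228 nm band.
# The basis spectra are synthetic stand-ins shaped like published peptide
# classes, not a fitted basis set.

suppressPackageStartupMessages(library(proisom))

wl <- seq(180, 260)
gauss <- function(mu, sd, amp) amp * exp(-(wl - mu)^2 / (2 * sd^2))
basis <- list(
  ppii = cd_spectrum(wl, gauss(228, 9, 4000) + gauss(196, 8, -22000),
                     "calculated"),
  other = cd_spectrum(wl, gauss(198, 10, -9000) + gauss(222, 12, -2500),
                      "calculated"))

fr <- read.csv("results/ss_fractions.csv")
pep <- fr[fr$residue == "peptide", ]
fracs <- c(ppii = pep$PPII, other = 1 - pep$PPII)
calc <- combine_basis(fracs, basis)
write_spectrum(calc, "results/cd_calculated.csv")

# synthetic in-vitro reference: same shape, 0.51x amplitude plus noise
set.seed(5)
meas <- cd_spectrum(wl, 0.51 * calc$mre + rnorm(length(wl), 0, 80),
                    "measured")
s <- scale_factor(calc, meas)
scaled <- apply_scale(calc, s)
write_spectrum(scaled, "results/cd_calculated_scaled.csv")
cat(sprintf("Least-squares scale factor calc -> measured: %.3f\n", s))

theta_228 <- function(sp) sp$mre[sp$wavelength_nm == 228]
cat(sprintf("Calculated spectrum: theta(228) = %.0f deg cm2/dmol -> PPII %.1f%%\n",
            theta_228(calc), ppii_from_ellipticity(theta_228(calc))))
cat(sprintf("Ensemble PPII fraction fed to the basis combination: %.1f%%\n",
            100 * fracs["ppii"]))
cat(sprintf("Reference conversions: theta = -796 -> %.1f%%, theta = -334 -> %.1f%%\n",
            ppii_from_ellipticity(-796), ppii_from_ellipticity(-334)))

smp <- sample_info(conc_M = 70e-6, path_cm = 0.1, n_residues = 12)
mdeg <- mre_to_millideg(meas$mre, smp)
back <- millideg_to_mre(wl, mdeg, smp)
cat(sprintf("Raw-signal round trip max error: %.2e deg cm2/dmol\n",
            max(abs(back$mre - meas$mre))))
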