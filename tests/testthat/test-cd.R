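test_that("millidegree conversion follows the mean-residue-ellipticity formula", {
  smp <- sample_info(conc_M = 70e-6, path_cm = 0.1, n_residues = 12)
  wl <- c(200, 228)
  z <- millideg_to_mre(wl, c(0, 0), smp)
  expect_equal(z$mre, c(0, 0))
  one <- millideg_to_mre(wl, c(1, 1), smp)
  # 100 * 0.001 / (12 * 70e-6 * 0.1) = 1190.476...
  expect_equal(one$mre, rep(100 * 0.001 / (12 * 70e-6 * 0.1), 2))
  expect_equal(one$mre[1], 1190.476, tolerance = 1e-6)
  dbl <- millideg_to_mre(wl, c(2, 2), smp)
  expect_equal(dbl$mre, 2 * one$mre)
  expect_error(sample_info(0, 0.1, 12))
})

test_that("mre conversion round-trips through its inverse", {
  smp <- sample_info(70e-6, 0.1, 12)
  set.seed(81)
  mdeg <- runif(50, -30, 30)
  sp <- millideg_to_mre(seq(180, 229), mdeg, smp)
  back <- mre_to_millideg(sp$mre, smp)
  expect_lt(max(abs(back - mdeg) / pmax(abs(mdeg), 1e-9)), 1e-12)
})

test_that("PPII content from the 228 nm band matches the calibration", {
  expect_equal(round(ppii_from_ellipticity(-796), 1), 38.7)
  expect_equal(round(ppii_from_ellipticity(-334), 1), 42.1)
  expect_equal(ppii_from_ellipticity(-6100), 0)
  # affine: two-point finite-difference slope is exactly 1/137
  slope <- (ppii_from_ellipticity(100) - ppii_from_ellipticity(0)) / 100
  expect_equal(slope, 1 / 137)
  expect_equal(ppii_from_ellipticity(0) - ppii_from_ellipticity(-137), 1)
})

test_that("scale factor is the least-squares ratio over the common grid", {
  wl <- seq(190, 250)
  base <- cd_spectrum(wl, sin(wl / 10) * 1000, "calculated")
  expect_equal(scale_factor(base, apply_scale(base, 2)), 2)
  expect_equal(scale_factor(base, base), 1)
  set.seed(82)
  noisy <- cd_spectrum(wl, 0.51 * base$mre + rnorm(61, 0, 5), "measured")
  s_closed <- sum(base$mre * noisy$mre) / sum(base$mre^2)
  expect_equal(scale_factor(base, noisy), s_closed, tolerance = 1e-12)
  # coarser reference gets interpolated onto the finer grid; a linear
  # spectrum makes the interpolation exact
  line <- cd_spectrum(wl, 5 * wl - 800, "calculated")
  coarse <- cd_spectrum(seq(190, 250, by = 5),
                        2 * (5 * seq(190, 250, by = 5) - 800), "measured")
  expect_equal(scale_factor(line, coarse), 2, tolerance = 1e-9)
  far <- cd_spectrum(seq(260, 270), rep(1, 11), "measured")
  expect_error(scale_factor(base, far), "overlap")
})

test_that("basis combination is the fraction-weighted pointwise sum", {
  wl <- seq(180, 260, by = 2)
  b1 <- cd_spectrum(wl, cos(wl / 15) * 800, "calculated")
  b2 <- cd_spectrum(wl, sin(wl / 20) * 600, "calculated")
  basis <- list(helix = b1, coil = b2)
  expect_equal(combine_basis(c(helix = 1, coil = 0), basis)$mre, b1$mre)
  half <- combine_basis(c(helix = 0.5, coil = 0.5), basis)
  expect_equal(half$mre, (b1$mre + b2$mre) / 2)
  mixed <- combine_basis(c(helix = 0.3, coil = 0.7), basis)
  expect_true(all(mixed$mre <= pmax(b1$mre, b2$mre) + 1e-12))
  expect_true(all(mixed$mre >= pmin(b1$mre, b2$mre) - 1e-12))
  expect_error(combine_basis(c(helix = 0.6, coil = 0.6), basis), "sum")
  expect_error(combine_basis(c(helix = 1), basis), "match")
  # long-format basis table round-trips through the same contract
  long <- rbind(data.frame(class = "helix", wavelength_nm = wl, value = b1$mre),
                data.frame(class = "coil", wavelength_nm = wl, value = b2$mre))
  expect_equal(combine_basis(c(helix = 0.5, coil = 0.5), long)$mre,
               half$mre)
})

test_that("spectrum files round-trip through read/write", {
  wl <- seq(190, 240)
  sp <- cd_spectrum(wl, rnorm(51, -500, 300), "calculated")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  back <- read_spectrum(path, "calculated")
  expect_equal(back$wavelength_nm, sp$wavelength_nm)
  expect_equal(back$mre, sp$mre, tolerance = 1e-12)
  expect_error(cd_spectrum(c(200, 200), c(1, 2)), "increasing")
  expect_error(cd_spectrum(c(100, 200), c(1, 2)), "170")
})
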