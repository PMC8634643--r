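test_that("exact weights reproduce closed forms and brute force", {
  kT <- kB * 300
  expect_equal(exact_weights(rep(0, 5))$w, rep(0.2, 5))
  w <- exact_weights(c(0, kT * log(2)))
  expect_equal(w$w, c(1 / 3, 2 / 3), tolerance = 1e-12)
  set.seed(31)
  dv <- runif(200, 0, 3)
  brute <- exp(dv / kT); brute <- brute / sum(brute)
  expect_equal(exact_weights(dv)$w, brute, tolerance = 1e-10)
  expect_equal(sum(exact_weights(dv)$w), 1, tolerance = 1e-12)
  # large boosts must not overflow
  expect_true(all(is.finite(exact_weights(c(0, 500, 1000))$w)))
  expect_error(exact_weights(c(1, -0.1)), ">= 0")
})

test_that("maclaurin weights interpolate between uniform and exact", {
  kT <- kB * 300
  set.seed(32)
  dv <- runif(300, 0, kT)  # beta*dV <= 1
  expect_equal(maclaurin_weights(dv, order = 0)$w,
               rep(1 / 300, 300))
  m10 <- maclaurin_weights(dv, order = 10)$w
  ex <- exact_weights(dv)$w
  # Taylor remainder bound e*(beta dV)^11/11! ~ 7e-8 at beta dV = 1
  expect_lt(max(abs(m10 - ex) / ex), 1e-7)
  expect_equal(maclaurin_weights(5, order = 3)$w, 1)
  expect_equal(sum(m10), 1, tolerance = 1e-12)
})

test_that("reweighted means recover averages and state probabilities", {
  x <- c(1, 2, 3, 4)
  expect_equal(reweighted_mean(x, uniform_weights(4)), mean(x))
  w <- exact_weights(c(0, 0, 1, 1))
  ind <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(reweighted_mean(ind, w), sum(w$w[ind]))
  expect_error(reweighted_mean(1:3, uniform_weights(4)), "length")
})

test_that("PMF estimators honour their contracts", {
  kT <- kB * 300
  set.seed(33)
  om <- runif(5e4, -180, 180)
  # uniform angles, uniform weights: flat profile
  flat <- pmf_from_weights(om, uniform_weights(5e4), bins = 30)
  expect_lt(max(flat$f, na.rm = TRUE), 0.1)
  expect_equal(min(flat$f, na.rm = TRUE), 0)
  # dV = 0 reduces the cumulant PMF to Boltzmann inversion of the histogram
  om2 <- c(rep(-10, 300), rep(170, 100))
  p0 <- pmf_cumulant2(om2, rep(0, 400), bins = 36)
  occ <- which(!is.na(p0$f))
  expect_equal(diff(p0$f[occ]), kT * log(3), tolerance = 1e-9)
  expect_equal(min(p0$f, na.rm = TRUE), 0)
  # empty bins carry the NA sentinel and are excluded from the min-shift
  expect_true(any(is.na(p0$f)))
})

test_that("weight-based PMF matches the quadrature free energy", {
  sp0 <- fixture_spec()
  sp <- calibrate_boost(sp0, 1)
  kT <- kB * 300
  tr <- sample_boosted_trajectory(sp, 4e5, seed = 17)
  prof <- pmf_from_weights(tr, exact_weights(tr), bins = 36)
  # reference free energy from bin-integrated quadrature probabilities
  edges <- seq(-180, 180, length.out = 37)
  p_ref <- vapply(seq_len(36), function(j) {
    oracle_state_prob(sp0, edges[j], edges[j + 1])
  }, numeric(1))
  f_ref <- -kT * log(p_ref); f_ref <- f_ref - min(f_ref)
  eff <- prof$wsum^2 / vapply(seq_len(36), function(j) {
    idx <- bin_index_for_test(tr$omega[, 1], edges) == j
    s <- sum(exact_weights(tr)$w[idx]^2); if (s == 0) 1 else s
  }, numeric(1))
  ok <- !is.na(prof$f) & eff >= 100
  expect_gt(sum(ok), 10)
  expect_lt(max(abs(prof$f[ok] - f_ref[ok])), 0.3)
})

test_that("cumulant-2 PMF recovers the ground-truth barrier", {
  sp0 <- torsion_potential(torsion_term(2, 4, 180))
  sp <- calibrate_boost(sp0, 1)
  tr <- sample_boosted_trajectory(sp, 4e5, seed = 19)
  prof <- pmf_cumulant2(tr)
  expect_equal(pmf_barrier(prof), 4, tolerance = 0.5 / 4)
  expect_equal(min(prof$f, na.rm = TRUE), 0)
})

test_that("anharmonicity vanishes for Gaussian boosts and flags bimodal ones", {
  set.seed(34)
  n <- 1e5
  om <- runif(n, -180, 180)
  dv <- pmax(rnorm(n, mean = 5, sd = 0.5), 0)
  rep_g <- anharmonicity(om, dv, bins = 20)
  expect_lt(abs(rep_g$average), 1e-2)
  # smaller sample: larger estimator bias; the average trends toward 0 with N
  rep_small <- anharmonicity(om[1:5000], dv[1:5000], bins = 20)
  expect_lt(abs(rep_g$average), abs(rep_small$average))
  # strongly bimodal boost distribution in every bin
  dv_b <- pmax(c(rnorm(n / 2, 2, 0.2), rnorm(n / 2, 8, 0.2)), 0)
  rep_b <- anharmonicity(om[sample(n)], dv_b, bins = 20)
  expect_gt(abs(rep_b$average), abs(rep_g$average))
  expect_gt(abs(rep_b$average), 0.1)
  # the documented cutoff drives the pass flag
  expect_identical(rep_g$pass, abs(rep_g$average) < 1e-3)
  expect_false(anharmonicity(om, dv_b[sample(n)], cutoff = 1e-3)$pass)
})

test_that("degenerate constant-boost bins report zero anharmonicity", {
  om <- runif(1000, -180, 180)
  repn <- anharmonicity(om, rep(2, 1000), bins = 10)
  expect_equal(repn$average, 0)
  expect_true(repn$pass)
})

test_that("estimator family agrees on near-Gaussian data and orders barriers", {
  sp0 <- torsion_potential(torsion_term(2, 4, 180))
  sp <- calibrate_boost(sp0, 1)
  tr <- sample_boosted_trajectory(sp, 4e5, seed = 23)
  b_c2 <- pmf_barrier(pmf_cumulant2(tr))
  b_mac <- pmf_barrier(pmf_from_weights(tr, maclaurin_weights(tr)))
  b_ex <- pmf_barrier(pmf_from_weights(tr, exact_weights(tr)))
  expect_lte(b_mac, b_c2 + 0.1)
  expect_equal(b_mac, b_ex, tolerance = 0.05)
})
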