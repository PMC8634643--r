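test_that("cosine-series potential evaluates to hand-computed values", {
  low <- torsion_potential(torsion_term(2, 15, 180))
  expect_equal(evaluate_potential(low, 180), 0)
  expect_equal(evaluate_potential(low, 90), 15)
  expect_equal(evaluate_potential(low, 0), 0)
  # hand sum: (20/2)(1+cos(-180)) + (2/2)(1+cos 0) = 0 + 2
  mix <- torsion_potential(list(torsion_term(2, 20, 180),
                                torsion_term(1, 2, 0)))
  expect_equal(evaluate_potential(mix, 0), 2)
  expect_equal(evaluate_potential(mix, 180), 0 + 0)
})

test_that("potential is periodic and wrapping-invariant", {
  sp <- fixture_spec()
  om <- seq(-180, 180, by = 7.3)
  expect_equal(evaluate_potential(sp, om),
               evaluate_potential(sp, om + 360))
  expect_equal(evaluate_potential(sp, om),
               evaluate_potential(sp, om - 720))
})

test_that("constructors validate their inputs", {
  expect_error(torsion_term(0, 5), "positive integer")
  expect_error(torsion_term(2, -1), ">= 0")
  expect_error(torsion_potential(list()), "non-empty")
  expect_error(boost_spec(4, -1), ">= 0")
  expect_error(torsion_potential(torsion_term(2, 4, 180), temperature = 0),
               "> 0")
})

test_that("boost energy follows the harmonic form and vanishes above E", {
  sp <- torsion_potential(torsion_term(2, 4, 180),
                          boost = boost_spec(3, 0.2))
  om <- seq(-179, 180, by = 1)
  u <- evaluate_potential(sp, om)
  dv <- boost_energy(sp, om)
  below <- u < 3
  expect_equal(dv[below], 0.5 * 0.2 * (3 - u[below])^2)
  expect_true(all(dv[!below] == 0))
  expect_true(all(dv >= 0))
})

test_that("barrier presets give the lowered and default barrier heights", {
  expect_equal(potential_barrier(peptide_torsion_preset("lowered")), 15,
               tolerance = 1e-8)
  expect_equal(potential_barrier(peptide_torsion_preset("default")), 20,
               tolerance = 1e-8)
})

test_that("analytic state probability matches symmetry and the dense oracle", {
  sym <- torsion_potential(torsion_term(2, 15, 180))
  # widening the cis range symmetrically to (-90, 90) makes it exactly half
  expect_equal(analytic_state_probability(sym, -90, 90), 0.5,
               tolerance = 1e-6)
  sp <- torsion_potential(list(torsion_term(2, 15, 180),
                               torsion_term(1, 2, 0)))
  p_cis <- analytic_state_probability(sp, -90, 50)
  expect_equal(p_cis, oracle_state_prob(sp, -90, 50), tolerance = 1e-5)
  # complement rule, including a wrapped interval
  expect_equal(p_cis + analytic_state_probability(sp, 50, -90), 1,
               tolerance = 1e-6)
  expect_equal(analytic_state_probability(sp, 30, 30), 0)
})

test_that("boost calibration hits the requested mean boost level", {
  sp <- calibrate_boost(fixture_spec(), 1)
  tr <- sample_boosted_trajectory(sp, 2e5, seed = 11)
  expect_equal(mean(tr$deltaV) / (kB * 300), 1, tolerance = 0.05)
  expect_error(calibrate_boost(fixture_spec(), 100), "unreachable")
})
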