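test_that("sampler requires a seed and is deterministic given one", {
  sp <- fixture_spec()
  expect_error(sample_boosted_trajectory(sp, 100), "seed")
  t1 <- sample_boosted_trajectory(sp, 500, seed = 42)
  t2 <- sample_boosted_trajectory(sp, 500, seed = 42)
  expect_identical(t1$omega, t2$omega)
  expect_identical(t1$deltaV, t2$deltaV)
  t3 <- sample_boosted_trajectory(sp, 500, seed = 43)
  expect_false(identical(t1$omega, t3$omega))
})

test_that("flat potential samples the circle uniformly", {
  flat <- torsion_potential(torsion_term(1, 0, 0))
  tr <- sample_boosted_trajectory(flat, 1e5, seed = 5, proposal_width = 180)
  ks <- suppressWarnings(
    stats::ks.test(tr$omega[, 1], "punif", -180, 180))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("unboosted equilibrium matches the quadrature oracle", {
  sp <- fixture_spec()
  tr <- sample_boosted_trajectory(sp, 4e5, seed = 9, proposal_width = 180)
  st <- classify_omega(tr$omega[, 1])
  p_hat <- mean(st == "cis") / mean(st != "unassigned")
  p_true <- oracle_state_prob(sp, -90, 50) /
    (oracle_state_prob(sp, -90, 50) + oracle_state_prob(sp, 100, 240))
  bs <- block_bootstrap_se((st == "cis") / mean(st != "unassigned"),
                           tr$deltaV, seed = 1)
  expect_lt(abs(p_hat - p_true), 3 * max(bs$se, 1e-3))
})

test_that("boosted run reweights back to the unbiased cis fraction", {
  sp0 <- fixture_spec()
  sp <- calibrate_boost(sp0, 1)
  tr <- sample_boosted_trajectory(sp, 4e5, seed = 21)
  w <- maclaurin_weights(tr)
  st <- classify_omega(tr$omega[, 1])
  p_hat <- reweighted_mean(st == "cis", w)
  p_true <- oracle_state_prob(sp0, -90, 50)
  bs <- block_bootstrap_se((st == "cis") / 1, tr$deltaV, seed = 2)
  expect_lt(abs(p_hat - p_true), 3 * max(bs$se, 5e-3))
})

test_that("recorded boost energies equal the recomputed harmonic boost", {
  sp <- calibrate_boost(fixture_spec(), 0.5)
  tr <- sample_boosted_trajectory(sp, 1e4, seed = 3)
  expect_equal(tr$deltaV, boost_energy(sp, tr$omega[, 1]),
               tolerance = 1e-12)
})

test_that("independent sites multiply, locked sites coincide", {
  specs <- list(fixture_spec(V1 = 0.8), fixture_spec(V1 = 1.2))
  # global (width-180) proposals decorrelate the chain across the barrier
  ind <- generate_multisite(specs, "independent", 2e5, seed = 6,
                            proposal_width = 180)
  st <- isomer_states(ind)
  p1 <- mean(st[, 1] == "cis"); p2 <- mean(st[, 2] == "cis")
  joint <- mean(st[, 1] == "cis" & st[, 2] == "cis")
  expect_lt(abs(joint - p1 * p2), 0.005)
  lock <- generate_multisite(specs, "locked", 5e4, seed = 6)
  expect_identical(lock$omega[, 1], lock$omega[, 2])
  stl <- isomer_states(lock)
  expect_equal(mean(stl[, 1] == "cis" & stl[, 2] == "cis"),
               mean(stl[, 1] == "cis"))
  expect_error(generate_multisite(specs, "banana", 10, seed = 1))
})

test_that("five independent sites give the product all-trans fraction", {
  specs <- fixture_five_sites()
  tr <- generate_multisite(specs, "independent", 2e5, seed = 13,
                           proposal_width = 180)
  st <- isomer_states(tr)
  all_trans <- mean(rowSums(st == "trans") == 5)
  p_trans <- vapply(specs, function(sp) {
    oracle_state_prob(sp, 100, 240)
  }, numeric(1))
  expect_lt(abs(all_trans - prod(p_trans)), 0.01)
})

test_that("emulated backbone labels round-trip through the classifier", {
  labs <- c(rep("PPII", 300), rep("PPI", 200), rep("other", 500))
  labs <- sample(labs)  # order must not matter
  bb <- emulate_backbone(labs, seed = 8)
  got <- assign_ppii_ppi(bb$phi, bb$psi, bb$omega)
  expect_identical(got, labs)
  frac <- ss_fraction_by_residue(got)
  expect_equal(frac$PPII[1], 0.3)
  expect_equal(frac$PPI[1], 0.2)
  expect_equal(frac$other[1], 0.5)
  expect_error(emulate_backbone(character(0), seed = 1), "non-empty")
  expect_error(emulate_backbone(c("PPII", "helix"), seed = 1), "unknown")
})

test_that("metropolis acceptance respects detailed balance on the boosted surface", {
  sp <- calibrate_boost(fixture_spec(), 1)
  kT <- kB * sp$temperature
  ustar <- function(w) evaluate_potential(sp, w) + boost_energy(sp, w)
  # acceptance ratio identity a(w->w')/a(w'->w) = exp(-(U*' - U*)/kT)
  for (pair in list(c(10, 60), c(170, -150), c(-90, -30))) {
    a_fwd <- min(1, exp(-(ustar(pair[2]) - ustar(pair[1])) / kT))
    a_bwd <- min(1, exp(-(ustar(pair[1]) - ustar(pair[2])) / kT))
    expect_equal(a_fwd / a_bwd,
                 exp(-(ustar(pair[2]) - ustar(pair[1])) / kT),
                 tolerance = 1e-12)
  }
})
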