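test_that("omega classification follows the canonical state ranges", {
  expect_equal(classify_omega(0), "cis")
  expect_equal(classify_omega(180), "trans")
  expect_equal(classify_omega(-150), "trans")  # 210 in the +100..+240 form
  expect_equal(classify_omega(75), "unassigned")
  expect_equal(classify_omega(-100), "unassigned")
  # half-open boundaries: lower edge in, upper edge out
  expect_equal(classify_omega(-90), "cis")
  expect_equal(classify_omega(50), "unassigned")
  expect_equal(classify_omega(100), "trans")
  expect_equal(classify_omega(-120), "unassigned")
  expect_error(classify_omega(NaN), "finite")
})

test_that("classification is invariant to 360-degree offsets", {
  set.seed(41)
  om <- runif(200, -180, 180)
  base <- classify_omega(om)
  for (k in sample(-10:10, 20, replace = TRUE)) {
    expect_identical(classify_omega(om + 360 * k), base)
  }
  # the wrapped trans convention: +100..+240 == +100..+180 U -180..-120
  expect_identical(classify_omega(seq(100.5, 239.5, by = 1)),
                   rep("trans", 140))
})

test_that("cis percentages are weighted, assigned-only, and sum with trans", {
  st <- c("cis", "cis", "trans", "unassigned")
  expect_equal(unname(cis_percentage(st)), 100 * 2 / 3)
  expect_equal(unname(cis_percentage(rep("cis", 4))), 100)
  w <- exact_weights(c(0, 0, 0, 0))
  expect_equal(cis_percentage(st, w), cis_percentage(st))
  trans_pct <- function(s, w = NULL) {
    s2 <- s; s2[s == "cis"] <- "trans"; s2[s == "trans"] <- "cis"
    cis_percentage(s2, w)
  }
  set.seed(42)
  sims <- matrix(sample(c("cis", "trans", "unassigned"), 300, TRUE),
                 ncol = 3)
  expect_equal(unname(cis_percentage(sims) + trans_pct(sims)),
               rep(100, 3))
  expect_error(cis_percentage(rep("unassigned", 5)), "no assigned")
})

test_that("flip counting bridges unassigned gaps and divides by the span", {
  st <- rep(c("cis", "trans"), 5)
  expect_equal(unname(flip_frequency(st, dt_ps = 0.1)), 9 / (0.9 / 1000))
  expect_equal(unname(flip_frequency(rep("cis", 10), 0.1)), 0)
  gap <- c("cis", "unassigned", "trans")
  expect_equal(unname(flip_frequency(gap, 0.1)), 1 / (0.2 / 1000))
  nogap <- c("cis", "unassigned", "cis")
  expect_equal(unname(flip_frequency(nogap, 0.1)), 0)
  # relabeling cis<->trans leaves the flip count unchanged
  set.seed(43)
  s <- sample(c("cis", "trans", "unassigned"), 500, TRUE)
  s2 <- chartr("a", "a", s)
  s2[s == "cis"] <- "trans"; s2[s == "trans"] <- "cis"
  expect_equal(flip_frequency(s, 0.1), flip_frequency(s2, 0.1))
  expect_error(flip_frequency("cis", 0.1), "2 frames")
})

test_that("weighted omega histogram is density-normalized", {
  set.seed(44)
  om <- runif(2e4, -180, 180)
  h <- omega_histogram(om, bins = 36)
  expect_equal(sum(h$density * 10), 1, tolerance = 1e-12)
  expect_lt(max(abs(h$density - 1 / 360)), 0.2 / 360 * 10)
  sp <- torsion_potential(torsion_term(2, 4, 180))
  tr <- sample_boosted_trajectory(sp, 2e5, seed = 45)
  h2 <- omega_histogram(tr)
  top <- h2$bin_center_deg[order(h2$density, decreasing = TRUE)[1:2]]
  expect_true(any(abs(top) < 30) && any(abs(abs(top) - 180) < 30))
})

test_that("joint distribution marginals are consistent", {
  st <- matrix(rep("cis", 6), ncol = 1)
  jd <- joint_distribution(st, rep(12, 6), breaks = c(10, 14))
  expect_equal(sum(jd), 1)
  expect_equal(jd["1", 1], 1)
  # marginal over n_cis equals the Poisson-binomial for independent sites
  specs <- fixture_five_sites()
  tr <- generate_multisite(specs, "independent", 1e5, seed = 46,
                           proposal_width = 180)
  st5 <- isomer_states(tr)
  obs <- rnorm(1e5, 25, 3)
  jd5 <- joint_distribution(st5, obs, breaks = 20)
  marg_ncis <- rowSums(jd5)
  p <- vapply(specs, function(sp) oracle_state_prob(sp, -90, 50),
              numeric(1))
  expect_lt(max(abs(marg_ncis - oracle_poisson_binomial(p))), 0.01)
  # marginal over the observable equals its weighted histogram
  br <- attr(jd5, "breaks")
  hist_w <- hist(obs, breaks = br, plot = FALSE)$counts / length(obs)
  expect_equal(unname(colSums(jd5)), hist_w, tolerance = 1e-12)
  expect_error(joint_distribution(st5, obs[-1]), "length")
})

test_that("running averages smooth with centered shrinking windows", {
  expect_equal(running_average(rep(3, 10), 5), rep(3, 10))
  x <- rnorm(20)
  expect_equal(running_average(x, 1), x)
  ramp <- seq_len(50)
  sm <- running_average(ramp, 7)
  expect_equal(sm[4:47], ramp[4:47])
  expect_error(running_average(x, 21), "exceeds")
})
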