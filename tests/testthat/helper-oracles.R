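# Independent oracles and shared fixtures. The quadrature oracle here is a
# deliberately naive dense trapezoid rule, kept separate from the package's
# adaptive quadrature so recovery tests have an independent reference.

# Boltzmann probability of [lo, hi] by dense trapezoid on a 0.01 degree grid
oracle_state_prob <- function(spec, lo, hi, grid = 0.01) {
  kT <- proisom::kB * spec$temperature
  om_all <- seq(-180, 180, by = grid)
  f_all <- exp(-proisom::evaluate_potential(spec, om_all) / kT)
  trap <- function(x, f) {
    if (length(x) < 2) return(0)
    sum((f[-1] + f[-length(f)]) / 2) * (x[2] - x[1])
  }
  seg <- function(a, b) {
    x <- seq(a, b, by = grid)
    trap(x, exp(-proisom::evaluate_potential(spec, x) / kT))
  }
  lo <- proisom::wrap_angle(lo); hi <- proisom::wrap_angle(hi)
  num <- if (hi > lo) seg(lo, hi) else seg(lo, 180) + seg(-180, hi)
  num / trap(om_all, f_all)
}

# Poisson-binomial pmf of the number of successes by direct convolution
oracle_poisson_binomial <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

# standard single-site fixture: lowered-barrier-like 2-fold term scaled to a
# desk-size barrier plus a 1-fold term that biases trans over cis
fixture_spec <- function(V2 = 4, V1 = 1, temperature = 300) {
  proisom::torsion_potential(
    list(proisom::torsion_term(2, V2, 180), proisom::torsion_term(1, V1, 0)),
    temperature = temperature)
}

bin_index_for_test <- function(omega, edges) {
  findInterval(proisom::wrap_angle(omega), edges, left.open = TRUE)
}

# five-site family with distinct trans biases (a five-proline peptide at
# desk scale)
fixture_five_sites <- function() {
  lapply(c(0.7, 0.9, 1.1, 1.3, 0.8), function(v1) fixture_spec(V1 = v1))
}
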