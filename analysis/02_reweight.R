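#!/usr/bin/env Rscript
# Stage 2: recover the unbiased free-energy landscape of the single-site
# run. Compares the second-order cumulant PMF with the Maclaurin-10
# weight-based PMF and runs the anharmonicity diagnostic on the boost
# energies. The ground-truth barrier of the synthetic model is 4 kcal/mol
# (plus the small 1-fold modulation), so estimator bias is directly visible.

suppressPackageStartupMessages(library(proisom))

tr <- read_trajectory("results/trajectories/single_site.csv")
cat(sprintf("Loaded %d frames, mean beta*deltaV = %.2f\n", n_frames(tr),
            mean(tr$deltaV) / (kB * tr$temperature)))

p_c2 <- pmf_cumulant2(tr)
w_mac <- maclaurin_weights(tr, order = 10)
p_mac <- pmf_from_weights(tr, w_mac)
p_ex <- pmf_from_weights(tr, exact_weights(tr))

write_pmf(p_c2, "results/pmf_cumulant2.csv")
write_pmf(p_mac, "results/pmf_maclaurin10.csv")
write_pmf(p_ex, "results/pmf_exact.csv")

cat(sprintf("Barriers (kcal/mol): cumulant-2 %.2f | maclaurin-10 %.2f | exact %.2f\n",
            pmf_barrier(p_c2), pmf_barrier(p_mac), pmf_barrier(p_ex)))
cat("The Maclaurin barrier should not exceed the cumulant-2 barrier",
    "(truncation damps the largest boosts).\n")

a <- anharmonicity(tr)
print(a)
write.table(a$table, "results/anharmonicity_bins.csv", sep = ",",
            quote = FALSE, row.names = FALSE)
cat("Note: on this generator deltaV is a deterministic function of omega,\n",
    "so per-bin boost distributions are far from Gaussian and the diagnostic\n",
    "is expected to flag them; on stochastic (engine-like) boosts it passes.\n",
    sep = "")

st <- classify_omega(tr$omega[, 1])
bs <- block_bootstrap_se((st == "cis") / 1, tr$deltaV, tr$temperature,
                         seed = 2)
sp0 <- torsion_potential(list(torsion_term(2, 4, 180), torsion_term(1, 1, 0)))
cat(sprintf("Reweighted p_cis = %.4f +/- %.4f (block bootstrap); quadrature %.4f\n",
            bs$mean, bs$se, analytic_state_probability(sp0, -90, 50)))
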