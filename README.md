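# proisom

Analysis of proline peptide-bond (ω) cis/trans isomerization in
boost-accelerated molecular dynamics ensembles.

Proline is the only residue with an appreciable *cis* peptide-bond
population, but the ~20 kcal/mol ω barrier hides isomerization from plain
MD. Accelerated-sampling runs add a harmonic boost
ΔV(r) = ½k(E − U(r))² below a threshold E, which flattens the barrier and
biases the ensemble; every equilibrium quantity must then be recovered by
reweighting frames with e^(βΔV). `proisom` is the downstream toolbox for
such runs, aimed at people studying proline-rich disordered peptides:

* **Reweighting** — exact exponential weights, Maclaurin-series weights
  (w ∝ Σₖ₌₀^K (βΔV)ᵏ/k!, K = 10 by default), and second-order cumulant
  PMFs F(ω) = −kT ln p_biased(ω) − [⟨ΔV⟩_ω + (β/2)σ²_ΔV,ω] + C, with a
  boost-energy **anharmonicity diagnostic** (entropy deficit vs. the
  Gaussian of equal variance, cutoff 10⁻³) and block-bootstrap errors.
* **ω-state analysis** — cis = [−90°, 50°), trans = [100°, 240°) on the
  circle; reweighted cis percentages, flipping frequencies, histograms,
  and the joint distribution of (number of prolines in cis) × any scalar
  observable such as end-to-end distance.
* **Structure** — per-residue PPII/PPI assignment from canonical
  (φ, ψ, ω) boxes and proline ring pucker (up/down/planar) from χ₂.
* **Correlation** — expected (product of marginals) versus observed joint
  cis occupancy for every subset of sites, with across-replicate spread.
* **CD utilities** — millidegrees → mean residue ellipticity
  ([θ]MR = 100·θ_deg/(n·c·l)), PPII content from the 228 nm band
  (%PPII = (θ₂₂₈ + 6100)/137.00), least-squares spectrum scale factors,
  and fraction-weighted basis-spectrum combination.
* **Synthetic generator** — Metropolis sampling of Amber-form torsion
  potentials U(ω) = Σ (Vₙ/2)(1 + cos(nω − γₙ)) with the same harmonic
  boost and per-frame ΔV, so every estimator is validated against
  quadrature ground truth. Presets carry the default (V₂ = 20 kcal/mol)
  and lowered (15 kcal/mol) peptide-bond barriers.

## Worked example

Generate a boosted single-proline trajectory on a desk-scale barrier
(V₂ = 4 kcal/mol plus a 1-fold trans bias), reweight it, and compare with
the analytic equilibrium:

```r
library(proisom)

spec  <- torsion_potential(list(torsion_term(2, 4, 180),
                                torsion_term(1, 1, 0)))
boosted <- calibrate_boost(spec, target_mean_beta_dv = 1)
tr <- sample_boosted_trajectory(boosted, 4e5, seed = 20260920)

st <- classify_omega(tr$omega[, 1])
bs <- block_bootstrap_se((st == "cis") / 1, tr$deltaV, seed = 2)
cat(sprintf("reweighted p_cis = %.4f +/- %.4f, quadrature = %.4f\n",
            bs$mean, bs$se, analytic_state_probability(spec, -90, 50)))
#> reweighted p_cis = 0.1642 +/- 0.0228, quadrature = 0.1667

p_c2  <- pmf_cumulant2(tr)
p_mac <- pmf_from_weights(tr, maclaurin_weights(tr))
cat(sprintf("barriers: cumulant-2 %.2f, maclaurin-10 %.2f kcal/mol\n",
            pmf_barrier(p_c2), pmf_barrier(p_mac)))
#> barriers: cumulant-2 4.65, maclaurin-10 4.65 kcal/mol
```

The reweighted cis fraction lands within one bootstrap standard error of
the quadrature value, and both PMF estimators recover the ~4.5 kcal/mol
ground-truth barrier (4 from the 2-fold term plus the 1-fold modulation at
±90°). The CD calibration in the other direction:

```r
ppii_from_ellipticity(c(-796, -334))
#> [1] 38.71533 42.08759
```

i.e. PPII contents of 38.7% and 42.1% for ellipticities of −0.796×10³ and
−0.334×10³ deg·cm²·dmol⁻¹ at 228 nm.

## The analysis workflow

`analysis/` holds numbered drivers that run the whole study on synthetic
ensembles and write tables under `results/`:

1. `01_simulate.R` — boosted single-site and five-site (three-replicate)
   ensembles with analytically known per-site cis fractions;
2. `02_reweight.R` — PMFs (cumulant-2, Maclaurin-10, exact), barrier
   comparison, anharmonicity report;
3. `03_isomerization.R` — cis percentages ± replicate sd, flipping
   frequencies, ω histograms, joint (n_cis × end-to-end) distribution;
4. `04_structure.R` — PPII/PPI fractions by residue, pucker fractions;
5. `05_correlation.R` — all 26 site subsets, expected vs. observed joint
   cis, plus a locked maximal-correlation fixture;
6. `06_cd.R` — basis combination, 0.51 scale-factor recovery, PPII from
   the 228 nm band.

Run them in order with `Rscript analysis/01_simulate.R` etc. A single
`run_pipeline()` call (YAML-configurable, seeded, byte-reproducible)
chains the same stages for arbitrary input tables; `validate_inputs()`
checks third-party trajectory tables before ingestion.

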