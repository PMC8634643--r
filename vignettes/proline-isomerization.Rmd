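---
title: "Reweighting boosted torsional ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reweighting boosted torsional ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proisom)
```

## The problem

Proline is the one residue whose peptide bond populates the *cis* isomer
(ω ≈ 0°) appreciably, but the *cis*/*trans* barrier (~20 kcal/mol in common
force fields) makes isomerization essentially unobservable in plain MD.
Boost-accelerated sampling (a harmonic boost ΔV = ½k(E − U)² added wherever
the potential lies below a threshold E) flattens the landscape so flips
happen, at the price of a biased ensemble. `proisom` implements the
downstream analysis of such runs: recovering unbiased populations and free
energy profiles by reweighting, classifying ω states and polyproline
structure, testing whether multiple prolines isomerize cooperatively, and
relating ensembles to circular dichroism (CD) observables.

Because real boosted trajectories are too expensive to regenerate, the
package carries its own synthetic generator: Metropolis Monte Carlo on an
Amber-form cosine-series torsion potential
U(ω) = Σₙ (Vₙ/2)(1 + cos(nω − γₙ)) with the same harmonic boost. Its
unbiased equilibrium is known analytically (by quadrature of e^(−U/kT)), so
every estimator in the package can be validated against ground truth.

## The torsion model and presets

The 2-fold term alone sets the peptide-bond isomerization barrier: with
phase 180° both planar states are minima and the barrier sits at ±90°,
equal to V₂. `peptide_torsion_preset()` exposes the two conventional
choices — 20 kcal/mol (force-field default) and 15 kcal/mol (lowered, to
accelerate isomerization sampling). Adding a 1-fold term V₁ (phase 0°)
raises *cis* relative to *trans* by V₁, which is how the synthetic fixtures
obtain realistic *cis* fractions of roughly 10–25%.

Throughout, kB = 0.0019872041 kcal/(mol·K) and the default temperature is
300 K. Angles are degrees, wrapped to (−180, 180].

## Sampling choices

The generator is Metropolis Monte Carlo, not Langevin dynamics: only
equilibrium populations and reweighting are consumed downstream, and a
Markov chain removes integrator and thermostat choices that belong to the
MD engine. Consequences the reader should keep in mind:

* "Flipping frequencies" on synthetic data are per retained-frame time, a
  bookkeeping rate, not physical kinetics.
* Proposals are symmetric uniform perturbations of half-width
  `proposal_width` (default 30°, burn-in 10⁴ steps, every step retained).
  Local proposals mimic the slow barrier crossing of real dynamics; for
  equilibrium-property checks the width can be set to 180°, which proposes
  globally and decorrelates the chain across the barrier. The test suite
  uses the wide setting where the quantity under test is an equilibrium
  fraction, and the local setting where boost-assisted crossing itself is
  being exercised.
* Boost parameters are user-specified. `calibrate_boost()` mirrors what a
  practitioner would tune: threshold E = max U on a fine grid, and k solved
  (by root finding on the gentle branch — mean boost rises with k only
  until the boost starts inverting the landscape) so the *biased* ensemble
  mean of βΔV hits a target, default 1, a moderate and safely reweightable
  boost level.

A per-frame consistency invariant holds by construction and is tested:
the recorded ΔV equals ½k(E − U(ω))² recomputed from the stored angle.

## Reweighting estimators

Given per-frame boost energies ΔVⱼ, the unbiased average of any observable
is ⟨x⟩ = Σ wⱼ xⱼ with wⱼ ∝ e^(βΔVⱼ):

* `exact_weights()` — the exponential average, max-subtracted before
  exponentiation to avoid overflow. Statistically noisy when a few frames
  dominate.
* `maclaurin_weights()` — wⱼ ∝ Σₖ₌₀^K (βΔVⱼ)ᵏ/k!, the conventional
  10th-order truncation. Reaction-coordinate independent, hence usable for
  every downstream statistic; the truncation damps the largest boosts, so
  PMFs built from these weights tend to *underestimate* barrier heights
  while leaving well depths essentially intact (asserted as
  barrier(Maclaurin) ≤ barrier(cumulant-2) + 0.1 kcal/mol on near-Gaussian
  synthetic data). At the boost levels used here (βΔV ≲ 1.5) the remainder
  e·(βΔV)¹¹/11! is negligible and Maclaurin-10 is numerically
  indistinguishable from exact.
* `pmf_cumulant2()` — per ω-bin, F = −kT ln p_biased − [⟨ΔV⟩ + (β/2)σ²ΔV]
  + C, the exponential average through its first two cumulants. Accurate
  when ΔV is near-Gaussian within a bin; preferred for barrier heights.
  Bin statistics are computed over raw frames (unweighted), matching the
  practice of the standard reweighting toolkits; whether weighted bin
  statistics would be preferable is genuinely open, and the weight-based
  PMF route is provided for comparison.

PMF contracts: default 60 bins of 6° over (−180, 180] (the source
analyses do not state a binning; 6° resolves the well shapes at the frame
counts used here), empty bins carry an `NA` sentinel and never participate
in the min-shift, and the minimum over non-empty bins is exactly zero.

Standard errors come from a block bootstrap (20 contiguous blocks, 200
resamples by default): contiguous blocks absorb the sampler's
autocorrelation, and weights are re-derived within each resample so
normalization is honoured. Across-replicate standard deviations (ddof = 1)
are reported alongside, mirroring how spread is usually shown across
independent simulations.

## The anharmonicity diagnostic

Cumulant-2 reweighting is only trustworthy if ΔV is near-Gaussian where it
matters. `anharmonicity()` measures, per ω-bin, the entropy deficit
γ = S_gauss − S_emp between the maximum-entropy Gaussian at the bin's
variance and a histogram estimate of the boost-energy differential entropy
(Freedman–Diaconis bin width, Miller–Madow bias correction — the standard
plug-in estimator choices). The population-weighted average is compared
against a 10⁻³ cutoff. Two conventions deserve note:

* The population quantity is non-negative, but the finite-sample estimate
  fluctuates below zero (published analyses likewise report small negative
  values), so the cutoff is applied to |γ|.
* On this package's *synthetic* trajectories ΔV is a deterministic function
  of ω, so within a narrow bin its distribution is nothing like a Gaussian
  and the diagnostic rightly fails. That is a feature of the generator, not
  the estimator: engine boosts aggregate many degrees of freedom and are
  near-Gaussian. The diagnostic is therefore validated on constructed
  stochastic fixtures (Gaussian ΔV: |γ| < 10⁻² at 10⁵ frames, decreasing
  with N; bimodal ΔV: flagged), and the cumulant-2 PMF's accuracy on
  synthetic data is established directly against the known potential.

## State classification and structure

*cis* is ω ∈ [−90°, 50°) and *trans* ω ∈ [100°, 240°) on the circle
(equivalently [100°, 180°] ∪ (−180°, −120°) after wrapping); the barrier
gaps stay unassigned. Intervals are half-open at the upper edge purely for
deterministic tie-breaking — the source ranges are stated without endpoint
conventions, and no measurable mass sits on the boundary. Percentages
condition on assigned frames (so cis% + trans% = 100), and flip counting
bridges unassigned gaps rather than resetting, so a brief barrier
excursion during a crossing counts one flip, not two. The joint
simultaneous-*cis* occupancy uses the same conditioning (frames where every
subset site is assigned), which makes a fully locked fixture reproduce its
marginal exactly.

Polyproline boxes: PPII requires φ ∈ [−104.6°, −46.6°],
ψ ∈ [107.9°, 165.9°] and trans ω; PPI the same φ, ψ ∈ [131°, 189°]
(wrapped past 180°) and cis ω. The printed trans range "+100 to +180 or
−180 to −120" and the footnote form "+100° to +240°" are the same set
after wrapping; the wrapped equivalence is adopted. Bounds are closed as
printed; half-open edges appear only where wrapping creates adjacency.
Assignment is per-frame, per-residue with no minimum run length — the
per-residue fractions being reproduced carry no consecutive-residue
requirement, though a helix of length one is a generous reading. Ring
pucker from χ₂: up > +10°, down < −10°, planar in between.

The backbone emulator draws (φ, ψ, ω) uniformly inside the requested box
(or outside both, by rejection, for "other"), guaranteeing exact label
round-trips — a fixture for the fraction bookkeeping, not a model of real
Ramachandran densities.

## Correlation analysis

For every subset of sites (sizes 2 up to all), the expected joint *cis*
percentage under independence is 100·Πpᵢ and is compared with the observed
reweighted simultaneous occupancy. No formal hypothesis test is attached:
each replicate is reweighted independently, replicates are averaged
unweighted, and non-overlap of ±1 sd intervals is read descriptively,
mirroring the bar-plus-error-bar presentation this analysis reproduces.
Whether expected-value error bars should propagate marginal uncertainty is
left open; both the per-replicate expected values and their sd are
reported so either reading is possible.

## CD utilities

Raw millidegrees convert to mean residue ellipticity via
[θ]MR = 100·θ_deg/(c_MR·l) with c_MR = n·c. PPII content from the 228 nm
band uses the empirical calibration %PPII = (θ₂₂₈ + 6100)/137.00; the
denominator is read as 137.00 — the printed worked values (−796 → 38.7%,
−334 → 42.1%) confirm that reading, and one published in-vitro row
(−1300 → 35.5%) is internally inconsistent with the formula by 0.5
percentage points, which this package does not attempt to patch.
`scale_factor()` is the closed-form least-squares scalar over the common
wavelength grid (coarser spectrum linearly interpolated; full overlap by
default, sub-range configurable since the originally used range is
unstated). `combine_basis()` implements only the convex combination of
user-supplied per-class basis spectra — basis-set derivation is an external
concern, and no third-party basis is bundled.

## Problem sizes and what the tests do (and do not) show

The validation suite runs at desk scale: a 2-fold barrier of 4 kcal/mol
(so both states are visited often), 10⁵–10⁶ frames, boosts calibrated to
mean βΔV ≈ 1, five-site chains with analytic per-site *cis* fractions of
0.11–0.24, and 2–4 replicates. At these sizes the pipeline recovers
quadrature *cis* fractions within bootstrap error, the cumulant-2 barrier
within 0.5 kcal/mol, and the independence product rule across all 26
subsets. Published *cis* percentages from solvated peptide simulations
(e.g. ~14%/~10% for a tetramer's two prolines, or an all-trans fraction
near a third for a five-proline peptide) depend on the full force field
and solvent and are *not* reproducible from the torsion model alone; the
synthetic recovery properties are the testable surrogate.

Other known limitations: the generator's ΔV is deterministic in ω (see
the anharmonicity note); no 2-D (φ, ψ) PMFs; no kinetic models beyond
flip counting; DSSP-style bend/turn/3₁₀ assignment is out of scope; and
the σ₀ boost-spread control of engine-side boost estimation has no
synthetic analogue here (boosts are specified or calibrated directly).

## Reproducibility

Every stochastic operation requires an explicit seed (`seed` arguments;
`run_pipeline()` threads one master seed through replicate sub-seeds), and
identical configuration plus seed yields byte-identical output tables.
The `analysis/` scripts are thin numbered drivers over these functions and
write their tables under `results/`.
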