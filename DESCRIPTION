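Package: proisom
Title: Proline Cis/Trans Isomerization Analysis for Boosted MD Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of proline peptide-bond (omega) cis/trans
    isomerization in boost-accelerated molecular dynamics ensembles:
    energy-boost reweighting via exact exponential, Maclaurin-series and
    second-order cumulant estimators with an anharmonicity diagnostic;
    omega-state classification, cis percentages and flipping frequencies;
    potential-of-mean-force profiles; polyproline II/I helix and proline
    ring-pucker assignment from backbone and side-chain dihedrals;
    multi-proline cis-correlation statistics; and circular-dichroism
    utilities including mean residue ellipticity conversion and empirical
    PPII quantification from the 228 nm band. Includes a Metropolis
    sampler for boosted torsion potentials with analytically known
    unbiased equilibria, used as ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
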