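Package: protolra
Title: Ensemble pKa Estimation for GPCR Activation States by Linear
    Response Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating macroscopic pKa values of buried
    titratable residues (such as the conserved Asp2.50 of class A G
    protein-coupled receptors) from conformational ensembles sampled with
    the residue fixed in its protonated and deprotonated forms.  Includes
    exact and Metropolis Monte Carlo titration of interacting-site models
    on a pH grid, per-conformation half-titration (pKhalf) extraction,
    the Henderson-Hasselbalch ensemble transform, the two-endpoint linear
    response approximation average with jackknife standard errors,
    bimodal pKhalf population splitting, activation-state geometry
    metrics (interhelical distances, NPxxY RMSD, A100 index, triangle
    pocket areas, side-chain torsions) driven by Ballesteros-Weinstein
    residue maps, and a synthetic-ensemble generator with an exact
    joint-partition-function oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
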