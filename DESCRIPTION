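Package: phfold
Title: pH- and Salt-Dependent Coarse-Grained Peptide Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained peptide model coupling an OPEP-style potential
    (flat-bottomed dihedral wells, Mie non-bonded interactions, pairwise and
    cooperative backbone hydrogen bonds) with shifted Debye-Hueckel
    electrostatics under a sigmoidal distance-dependent dielectric.  Charges
    are assigned from pKa values by Henderson-Hasselbalch titration, so
    conformational ensembles respond to pH and ionic strength.  Includes a
    simulated-annealing Metropolis Monte Carlo sampler over backbone
    dihedrals, greedy RMSD clustering with energy-ranked representative
    selection, a rule-based secondary-structure assigner, and PDB/FASTA
    input-output for the coarse-grained representation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
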