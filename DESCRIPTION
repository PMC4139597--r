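Package: mfcg
Title: Mean-Field Coarse-Grained Modelling of Proteins, Nucleic Acids and Polysaccharides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified coarse-grained simulation engine for the three major
    biopolymer classes. Chains are reduced to virtual-bond traces (C-alpha,
    sugar-ring or glycosidic-oxygen anchors) carrying polar interaction sites
    whose charge distributions are represented as point dipoles rotating about
    the virtual-bond axes. Site-site potentials are mean-field (Boltzmann
    averaged) dipole-dipole interactions, anisotropic Gay-Berne contacts and
    Debye-Hueckel screened electrostatics, with temperature-dependent
    multipliers on the higher-order cumulant terms. Includes the restricted
    free energy / Kubo cluster-cumulant machinery used to derive such
    potentials on toy systems, a Langevin integrator with an adaptive
    multiple-time-step scheme, multiplexed temperature replica exchange,
    binless WHAM reweighting with melting-curve analysis, Kabsch
    superposition, conformational clustering, and FASTA/PDB-trace I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
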