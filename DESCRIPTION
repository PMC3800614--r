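Package: fccfold
Title: Genetic Algorithm Protein Structure Prediction on the FCC Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio on-lattice protein structure prediction on the
    three-dimensional face-centred-cubic (FCC) lattice. Conformations are
    self-avoiding walks scored either with the binary hydrophobic-polar (HP)
    contact model or with the empirical Berrera et al. 20x20 residue
    contact-potential matrix (BM). The search engine is a genetic algorithm
    with exhaustive operator application, duplicate-free populations, a
    hydrophobic-core-directed macro-mutation operator that mixes the
    low-resolution HP classification into a high-resolution BM search, and a
    pull-move random walk for stagnation recovery. Also provides the
    evaluation machinery: distance-matrix RMSD, relative-improvement
    percentages, contact-class accounting, progress-trace summaries, packaged
    benchmark proteins with literature reference values, and exhaustive
    small-chain enumeration oracles.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    seqinr,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
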