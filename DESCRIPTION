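Package: fracnmr
Title: Planning and Analysis of Fractionally 13C-Labeled Protein NMR Samples
Version: 0.1.0
Authors@R: person("fracnmr", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for biosynthetically directed fractional 13C labeling of
    proteins grown on mixtures of U-13C6 and unlabeled glucose. Predicts
    per-amino-acid 13C labeling statistics (intact-bond probabilities,
    conditional labeling, methyl multiplet fine structure, expected CB/CA
    peak-intensity ratios) from precursor-map enumeration; computes the
    CB(i)/CA(i) statistic and stereospecific methyl calls from assigned peak
    lists; fits 15N T1/T2 relaxation decays and estimates rotational
    correlation times; analyzes chemical-shift-perturbation titrations;
    compares multi-model structure ensembles (Kabsch superposition, mean
    structures, bundle RMSD matrices, per-residue global displacement); and
    costs isotope labeling media recipes. Includes seeded synthetic-data
    generators for every input type and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
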