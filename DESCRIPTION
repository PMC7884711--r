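Package: cppscreen
Title: Screening, Modeling and Design of Bacterial Cell-Penetrating Peptides
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing screens of cell-penetrating peptides (CPPs) in
    bacteria: peptide sequence validation and FASTA/table input-output with a
    case-encodes-chirality convention, a 505-dimensional sequence descriptor set
    (amino-acid composition, dipeptide composition, and an 85-scale per-residue
    index battery), physicochemical profiling (net charge, isoelectric point,
    GRAVY hydropathy, disorder proxy), Pearson-correlation feature selection with
    a top-n sweep, seeded random-forest regression of log10 penetration
    efficiency with 10-fold cross-validation, cutoff-based efficiency and
    toxicity classification, descriptive screen analytics, model-guided de novo
    CPP generation and ranking, a calibrated synthetic screen generator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
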