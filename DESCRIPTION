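Package: glapred
Title: Sequence- and Structure-Based Prediction of Protein
    Gamma-Glutamyl Carboxylation Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies gamma-carboxyglutamate (Gla) sites on glutamate
    residues from protein sequence and predicted structure.  Extracts
    glutamate-centred sequence windows, removes redundancy by two-stage
    homology reduction, encodes positional weighted matrix, amino acid
    composition, solvent accessibility and secondary structure features,
    and trains a radial-basis-function support vector machine evaluated by
    stratified k-fold cross-validation and independent testing.  Includes
    position-specific composition analyses and a seeded synthetic
    benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
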