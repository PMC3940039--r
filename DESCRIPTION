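Package: noemix
Title: Conformer Populations from Methyl NOEs and 15N Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structure-based analysis of two-state side-chain conformational
    equilibria in proteins by NMR. Predicts relative methyl-to-probe NOESY
    cross-peak volumes from crystal structures using a three-site methyl-jump
    generalized order parameter (with methyl-carbon and mean-proton centroid
    approximations), fits two-conformer population admixtures to experimental
    NOE volume tables, performs simple and extended Lipari-Szabo model-free
    fits of 15N R1/R2/heteronuclear-NOE data, evaluates two-site jump order
    parameters, converts state populations into free-energy differences, and
    correlates structure-based differential chemical-shift predictions with
    conformational-exchange linebroadening. A synthetic-data generator builds
    two-conformer test scenes with known populations and noise for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
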