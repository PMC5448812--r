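Package: meiokit
Title: Quantitative Analysis of Meiotic Crossover Genetics and Protein-DNA Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the quantitative assays used to characterize the
    yeast MutL-gamma (Mlh1-Mlh3) complex. Provides tetrad classification from
    spore-autonomous fluorescence patterns, Perkins map distances with delta-method
    standard errors, meiosis-I nondisjunction statistics, hydroxyl-radical footprint
    mapping from gel lane traces to protein residue coordinates via quartic
    molecular-weight calibration, atomic force microscopy particle volumetrics with
    oligomer classification, cooperative (Hill) binding and Michaelis-Menten kinetic
    fits, exact and likelihood-ratio contingency statistics, and seeded synthetic-data
    generators with ground truth for every assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    signal,
    EBImage,
    Biostrings,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
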