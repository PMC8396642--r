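Package: bemetab
Title: Annotation of Bemethyl Urinary Metabolites from LC-MS/HRMS Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying urinary metabolites of the actoprotector
    bemethyl (2-(ethylthio)benzimidazole) from high-resolution tandem mass
    spectrometry peak tables. Provides elemental-formula arithmetic and exact
    ion mass computation, isotopologue pattern convolution with sulfur-count
    inference, molecular-formula decomposition from accurate mass, an
    executable biotransformation rule network with pathway-probability
    scoring, precursor and product-ion annotation with neutral-loss labelling
    and retention-time based tautomer resolution, a geometric
    glutathione-conjugation reactivity screen on docked ternary complexes,
    and a simulator of extracted-ion chromatograms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
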