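Package: honeyvola
Title: Volatilome-Based Geographical Origin Authentication of Citrus Honey
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for authenticating the geographical origin of
    citrus honey from its headspace volatilome as measured by HS-SPME/GC-MS.
    Covers internal-standard semi-quantification of peak tables, linear
    (temperature-programmed) retention indexing against an n-alkane ladder,
    per-compound ANOVA and one-way MANOVA screening with observed-power and
    sample-size analysis, canonical linear discriminant analysis with
    tolerance screening, Bartlett chi-square chain, structure-matrix
    discrimination power and leave-one-out classification, Kaiser-criterion
    principal component analysis, and the marker-ratio geographic-origin
    index (ratio of selected marker-compound content to total volatile
    content). Ships a machine-readable group-summary table of 41 volatile
    compounds across five honey origins and a synthetic-data generator with
    that table's statistical structure, so every stage is testable without
    raw chromatograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, grDevices
Suggests: testthat (>= 3.0.0), MASS, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
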