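Package: karyostat
Title: Quantify and Compare Numerical Chromosomal Variation in Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies, visualizes, and statistically compares numerical
    chromosomal variation between experimentally defined groups of single
    cells. Reads per-cell chromosome counts from FISH tables, ISCN karyotype
    strings (SKY), or binned copy-number state matrices from single-cell
    whole-genome sequencing callers, reduces them to a common cell-by-
    chromosome matrix, and computes six population-level aneuploidy
    statistics: the instability index, ANCA and normalized ANCA, the
    aneuploidy and heterogeneity scores, and ploidy-class proportions.
    Group differences are tested by permutation of cell labels with
    Benjamini-Hochberg correction, and results are rendered as scatter,
    ternary, bivariate-percentage, and copy-number heatmap figures
    exportable to a multi-page PDF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite
Config/testthat/edition: 3
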