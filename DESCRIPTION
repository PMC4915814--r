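Package: gbex
Title: Quantitative Analysis of Germband Extension in Tracked Epithelial Cell Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing convergent extension of the Drosophila
    germband from tracked apical cell meshes: junctional Myosin II polarity
    quantification (exact Fourier decomposition and constrained double-Gaussian
    fits of castellated perimeter signals, with modal-background subtraction
    and doming correction), tissue/cell-shape/intercalation strain-rate
    decomposition, productive T1 neighbour-exchange detection with debouncing,
    Voronoi-deviation geometric stress, parasegment boundary statistics
    (Myosin comparisons with mixed-model ribbons, interface co-alignment,
    cells-per-parasegment, interface-fate classification), a combinatorial
    receptor-code robustness score with exhaustive pattern search, and a
    vertex-model simulator of axis extension with four line-tension laws.
    A synthetic-data generator produces every input the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    stats,
    utils,
    generics,
    pracma,
    lme4,
    lmerTest
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
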