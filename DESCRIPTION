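Package: mifqc
Title: Validation Statistics for Multiplex Immunofluorescence Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control statistics for multiplex immunofluorescence (mIF)
    panel validation from per-cell segmentation exports: marker positivity
    gating with global or per-run (local) Otsu intensity thresholds,
    combinatorial phenotype calling, 1-plex vs 4-plex concordance via
    Bland-Altman relative differences, intra- and inter-run coefficient of
    variation, the multiplex labeling efficiency (MLE) metric, and directional
    nearest-neighbor cell-cell distance reproducibility. Includes a synthetic
    tissue-section generator that emulates serial-section study designs with
    lognormal intensity populations and per-run multiplicative batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
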