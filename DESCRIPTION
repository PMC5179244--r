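Package: nosweep
Title: Node Overlap and Segregation Statistics in Moving Landscape Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial ecological structure of species
    assemblages from point occurrence records. Pairwise node overlap scores
    between species (or sites) of a binary presence-absence matrix are
    standardized against their hypergeometric expectation so that +1 marks
    perfect nestedness and -1 complete segregation; the matrix-level mean
    (nbar), its Z test, and the score standard deviation (modularity) are
    computed inside a 1 degree moving window of 0.1 degree cells stepped
    across a landscape. Includes generators for synthetic landscapes with
    controllable nestedness, modularity and segregation, projection of plot
    locations onto potential-natural-vegetation polygon maps, habitat-mask
    filtering, actual-versus-potential difference maps, per-ecoregion
    aggregation, intact-forest Welch contrasts, and a record-subsampling
    sensitivity analysis.
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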