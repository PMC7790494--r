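Package: ccntax
Title: Common Cell Type Nomenclature for Cell Type Taxonomies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for applying the Common Cell Type Nomenclature (CCN) to
    cell type taxonomies derived from single-cell and bulk transcriptomics
    (or any other quantitative modality). Mints and validates taxonomy ids
    and cell set accession ids, derives cell sets from hierarchical
    dendrograms or flat cluster lists, supports the manual annotation round
    trip (aliases, anatomical structures, ontology tags), maps cells to
    cell sets as a binary (or probabilistic) membership matrix, validates
    cortical aligned-alias names against a controlled vocabulary, and links
    cell sets across taxonomies through shared aligned aliases and parsed
    cross-taxonomy label references.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    optparse,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
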