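Package: trophicspace
Title: Trophic Metanetworks: Laplacian Trophic Levels, Diffusion-Kernel
    Layouts and Network Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses trophic metanetworks: a regional metaweb
    (directed, connected food web of potential interactions) together with
    the local food webs induced by site- or time-specific abundances.
    Computes trophic levels from the Laplacian of the symmetrised web,
    lays networks out in two dimensions with the x-axis pinned to trophic
    level and the y-axis embedded from a graph diffusion kernel by a
    constrained t-SNE ('TL-tsne', plus a grouped variant for large webs),
    aggregates networks over nested trophic groupings, and compares local
    webs through difference networks, structural metrics and Hill-number
    diversity and dissimilarity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    ggplot2,
    withr,
    stats,
    utils
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
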