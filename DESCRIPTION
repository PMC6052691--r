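Package: coremicro
Title: Core and Transient Microbiome Analysis for Longitudinal Anaerobic Digester Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for occurrence-based core/transient partitioning of OTU
    count tables from longitudinal multi-reactor amplicon surveys, with the
    supporting pipeline: mothur shared-file input and output, per-sample
    subsampling to fixed depth, inverse Simpson diversity and evenness,
    rarefaction and rank-abundance curves, Bray-Curtis and Jaccard community
    dissimilarities and temporal stability summaries, ANOSIM permutation
    tests, NMDS ordination and distance-based clustering, and a
    Dirichlet-multinomial generator of synthetic reactor surveys with planted
    core/transient labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
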