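Package: goloc
Title: Multi-Label Protein Subcellular Localization from Gene Ontology Term Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular localization of multi-location proteins
    from Gene Ontology (GO) annotations. GO terms retrieved for a protein's
    accession and for the accessions of its BLAST homologs are mapped onto a
    term-frequency (or binary) vector over the GO subspace spanned by the
    training proteins, and classified by one-vs-rest support vector machines
    with a multi-label decision rule: every class with a positive fused score
    is predicted, falling back to the top-scoring class when none is positive.
    Includes a direct table-lookup baseline over essential and child cellular
    component GO terms, multi-label evaluation metrics (locative and actual
    accuracy, over/equal/under-prediction distributions), leave-one-out cross
    validation, and a synthetic dataset generator with controllable class
    signatures, annotation depth and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
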