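Package: ihcscore
Title: Scoring and Prioritization of Cancer Marker Candidates from
    Immunohistochemistry Staining Annotations
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies ordinal immunohistochemistry (IHC) staining
    annotations (Intensity and Quantity) from antibody-based tissue
    profiling resources into numeric protein expression levels, and
    prioritizes cancer marker candidates per antibody and per
    cancer-to-normal tissue mapping. Expression in the mapped normal cell
    type (EiN) and the mean expression across cancer patients (EiC) give
    an expression difference (ED); z-score normalization of ED across
    antibodies within a mapping (significance, SG) and across mappings
    within an antibody (specificity, SP) yields a final antibody score
    EiC * SG * SP on the 0-225 scale. Includes top-k validation by
    one-sample t-tests, an ED heat-map matrix, fold-change-based candidate
    filtering rules with eight rule combinations, and a seeded synthetic
    annotation/cohort generator with planted ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    pheatmap
biocViews: Proteomics, BiomedicalInformatics, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
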