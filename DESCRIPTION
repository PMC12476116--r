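Package: inflamap
Title: Linking Peripheral Inflammation to Brain Imaging Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for relating a serum inflammation
    marker (C-reactive protein, CRP) to gray-matter function (fractional
    amplitude of low-frequency fluctuations, fALFF) and white-matter
    integrity (skeletonized diffusion metrics), and for annotating the
    resulting statistic maps with regional gene expression, neurotransmitter
    maps, and behavioral-domain maps. Inference uses permutation-based
    cluster-extent and threshold-free cluster enhancement (TFCE) family-wise
    error control, spatial-autocorrelation-preserving surrogate maps for
    cross-region correlations, ensemble nulls for gene-category enrichment,
    partial least squares regression on regional expression, and percentile
    bootstrap mediation of marker-to-behavior effects through imaging.
    Ships a synthetic-data generator with planted effects so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
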