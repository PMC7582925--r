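Package: crossdeconv
Title: Cross-Species Cell-Type Deconvolution of Bulk Brain Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates cell-type proportions in bulk brain expression
    samples (microarray or RNA-seq) from single-cell reference profiles,
    completing human reference signatures with mouse cell types where
    human data lack them. Implements sample-wise z-score normalization,
    four-stage feature selection (noise-model gene selection, mRMR
    reduction, homolog matching, rank-concordance banding), signature
    construction, ordinary-least-squares and NMF-regression proportion
    estimation, pseudo-bulk simulation validation, spatial smoothing and
    region clustering, donor-consistency analysis, connectivity-adjusted
    neuron/non-neuron ratio reconciliation with nuclei counts, and
    correlation of cell-type proportions with Alzheimer's clinical
    traits. Includes a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
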