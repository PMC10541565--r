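Package: molstage
Title: Molecular Phenology Staging of Fruit Development from Time-Series Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds a molecular phenology scale from replicate-level gene
    expression time series and projects new transcriptomic samples onto it.
    The pipeline screens a transcriptome down to a development-associated
    core gene set, smooths per-series expression profiles with LOESS,
    reduces the smoothed matrix by principal component analysis, fits a
    Bezier curve through the stage-associated component scores, and
    graduates the curve into evenly spaced molecular stages. Arbitrary
    expression matrices, including reduced marker-gene panels with
    loading-sign imputation, can then be mapped onto the frozen scale.
    Includes stage-by-time analytics (stage progression rates, growing
    degree days, Lin's concordance, stage-shift statistics), gradient
    boosting based selection of stage-associated transcripts, reduced
    core-set panel construction from component loadings, and a synthetic
    data generator with known latent developmental structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
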