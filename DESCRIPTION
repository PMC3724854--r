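Package: rnpls
Title: Recursive N-Way Partial Least Squares for Tensor Data Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Blockwise recursive N-way partial least squares (RNPLS)
    regression for tensor-valued inputs and outputs, with a forgetting
    factor for adaptive modelling of non-stationary processes such as
    brain-computer interface (BCI) calibration.  Includes the batch
    N-way PLS engine, comparison baselines (ordinary PLS with
    orthonormal scores, blockwise recursive PLS, unfolded PLS,
    multi-pass iterative NPLS), a synthetic two-class tensor data
    generator with Kronecker-structured noise, evaluation utilities
    (RMSE, scale/sign-invariant coefficient distances, Welch's t-test,
    modality-influence profiles, cross-validated factor selection,
    benchmark scenarios), and continuous-wavelet-transform feature
    tensor construction for multichannel electrophysiology.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
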