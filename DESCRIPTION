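Package: collmapnet
Title: Collateral Perfusion Map Regression from Dynamic Susceptibility
    Contrast MR Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for five-phase collateral perfusion mapping in acute
    ischemic stroke from 4D dynamic susceptibility contrast MR perfusion
    (DSC-MRP). Provides readers and writers for 4D NIfTI series, the
    preprocessing chain (brain masking, min-max normalization, median
    filtering, center cropping), semi-automatic phase ground-truth
    generation from arterial and venous signal-time curves, a lightweight
    3D mobile convolution/Transformer encoder-decoder regression network
    trained with the reverse Huber (BerHu) loss, evaluation metrics
    (R-squared, MAE, Tanimoto, SSIM), static parameter/FLOP profiling,
    and a synthetic gamma-variate bolus phantom generator for testing
    every component without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
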