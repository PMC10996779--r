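Package: optiqat
Title: Quantization-Aware Training of Diffractive Optical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Differentiable simulator for phase-only diffractive deep neural
    networks (D2NNs) together with a family of quantization-aware training
    (QAT) methods for their phase coefficients. Free-space propagation between
    layers uses the band-limited angular-spectrum method; gradients through
    propagation, modulation and the quantizers are analytic and
    finite-difference audited. Quantizers include hard quantization,
    progressive sigmoid quantization (PSQ) with fixed, linearly increasing or
    learnable temperature, tanh-based differentiable soft quantization (DSQ),
    the straight-through estimator (STE), Gumbel-Softmax relaxation, and
    post-quantization. Includes two physics-based objectives (patch-readout
    phase-object classification and all-optical quantitative phase imaging),
    a two-stage full-precision to QAT training pipeline, SSIM and phase-error
    evaluation, and a synthetic phase-object generator so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
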