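Package: visnoise
Title: Stress-Testing Visual Recognition with SSNR-Controlled Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the robustness of visual recognition systems
    to image noise. Generates pixelated Gaussian and Fourier phase-scrambled
    noise stimuli blended with object images at controlled signal-to-signal-
    plus-noise ratios (SSNR), trains compact convolutional networks on
    mixtures of clean and noisy images, fits four-parameter logistic
    psychometric functions to extract SSNR thresholds, quantifies layer-wise
    noise susceptibility and training-induced weight change (canonical
    correlation), computes layer-wise relevance propagation heatmaps for
    diagnostic-feature comparison with human observers, and analyses
    run-structured multivoxel response patterns with leave-one-run-out
    decoding and representational similarity analysis. Includes synthetic
    generators for procedural object images, simulated observers, and
    simulated voxel patterns with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    e1071,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
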