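Package: kandiff
Title: Conditional Diffusion Denoising of Single-Lead ECG with
    Kolmogorov-Arnold Spline Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A conditional denoising diffusion probabilistic model (DDPM)
    for fixed-length single-lead electrocardiogram segments, in which the
    feature-wise affine (FiLM-style) conditioning layers of the denoising
    backbone are Kolmogorov-Arnold network (KAN) B-spline transforms with
    dedicated activation-sparsity and entropy regularization.  Includes
    uniform B-spline basis evaluation by the Cox-de Boor recursion, a
    multi-scale residual convolutional backbone with switchable linear/KAN
    conditioning, quadratic beta noise schedules, multi-shot averaging
    inference, standard ECG fidelity metrics (SSD, MAD, PRD, cosine
    similarity), a synthetic generator for clean PQRST beats mixed with
    baseline-wander, EMG-like and powerline noise under record-disjoint
    splits, and a command-line interface for simulate/train/denoise/evaluate
    pipelines driven by YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    data.table
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
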