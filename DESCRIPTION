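Package: cdd
Title: Causal Network Inference with Diffusion Models and Do-Calculus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers directed causal networks from cross-sectional
    samples-by-variables matrices. A denoising diffusion model is trained
    on the joint data distribution; candidate causes are intervened on at
    the hidden (noised) layer via a do-calculus backdoor adjustment, and
    each directed edge is accepted or rejected by comparing generation
    errors under the causal (H1, intervene with observed values) and
    non-causal (H0, intervene with Gaussian noise) hypotheses. Includes
    readers and writers for benchmark-style expression matrices and gold
    standard edge lists, K-fold edge testing, AUROC/AUPR evaluation, a
    synthetic structural-equation data generator with known ground truth,
    and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
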