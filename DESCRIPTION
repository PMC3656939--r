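Package: hardigm
Title: Grey-Matter Fingerprinting from High Angular Resolution Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based analysis of high angular resolution diffusion
    imaging (HARDI) signals in cortical grey matter. Fits an even-order
    spherical-harmonic model to per-vertex apparent diffusion coefficient
    (ADC) profiles sampled at cortical mid-thickness, derives a 27-element
    vector of orientationally referenced and fully rotation-invariant
    features of the profile, and discriminates cortical tissue classes with
    supervised (support-vector machine, three-way and pairwise) and
    unsupervised (ordered k-means) classification. Includes a synthetic
    multi-tensor HARDI phantom generator over a folded two-surface cortical
    ribbon with Rician noise for test/retest experiments, and readers and
    writers for NIfTI-1 volumes, FSL-dialect gradient tables, ASCII OFF
    meshes and tabular per-vertex records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
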