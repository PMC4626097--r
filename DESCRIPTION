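Package: atrophynet
Title: Network-Diffusion Models of Regional Atrophy Spread on Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits two competing linear network-diffusion models of regional
    gray-matter atrophy to group volumetrics on a structural connectome: a
    spread-of-activity (excitotoxicity) model whose atrophy prediction is a
    partial eigen-mode expansion of the Laplacian pseudo-inverse applied to a
    seed, and a time-resolved spread-of-atrophy (progressive degeneration)
    model given by the integrated heat kernel. Includes derivation of measured
    atrophy from cohort volumetrics (side-flipping to an ipsilateral
    convention, two-sample t-statistics), correlation sweeps over eigen-mode
    count, seed region and diffusion depth, a peak-versus-monotone model
    comparison criterion, permutation null distributions with per-permutation
    re-optimization of the free parameter, and a synthetic bilateral
    connectome and cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
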