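Package: tabvis
Title: Headless Engines and Psychometric Evaluation for Tablet-Based Tests of Real-World Visual Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Headless, seedable re-implementations of two tablet-based tests
    of real-world visual function: a QUEST-driven four-alternative
    forced-choice face-discrimination threshold test operating on a
    landmark-space dissimilarity axis, and a 7x9-grid visual-search
    response-time test. Includes generative simulated observers, a synthetic
    cohort generator, and the complete psychometric evaluation pipeline:
    Bland-Altman test-retest repeatability with BCa bootstrap confidence
    intervals, trials-versus-precision refinement curves, normative reference
    limits (Gaussian and Gamma maximum-likelihood fits with 99% cutoffs),
    pointwise per-location norms with an eccentricity power-law fit, and
    covariate association tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
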