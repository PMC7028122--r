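# tabvis

Headless, seedable engines for two tablet-style tests of real-world
visual function, plus the psychometric evaluation pipeline used to
characterise them.

Clinical vision research increasingly wants quick, patient-friendly
measures of *functional* vision — how well someone can tell faces apart,
or find an object in clutter — to complement acuity charts and
patient-reported outcome measures. This package re-implements two such
tests as screen-free simulation engines, so that their statistical
machinery can be developed, stress-tested and calibrated without a
tablet or a participant:

* **Faces** — a four-alternative forced-choice ("odd one out")
  discrimination task driven by a Bayesian adaptive (QUEST-family)
  staircase. Difficulty is the dissimilarity *d* between standard and
  target, the Euclidean distance between their 127-point landmark
  vectors. The outcome is the posterior-mean threshold, in d-units,
  updated after every one of 50 trials; the assumed psychometric
  function is a Weibull with guess rate 0.25.
* **Search** — a find-the-matching-object task on a 9 × 7 grid tiling a
  26 cm × 17.3 cm screen viewed at 50 cm. Each of the 62 non-centre
  locations is tested exactly once in seeded random order; the outcome
  is the median response time (seconds) across locations, whose mean
  rises with target eccentricity as a power law
  `RT = a·ecc^b + c`.

Around the engines sits the full evaluation pipeline: Bland–Altman
test-retest repeatability (bias, limits of agreement, CoR95 = 1.96 × sd
of paired differences) with BCa bootstrap confidence intervals (20 000
resamples, pairs resampled to preserve pairing); refinement curves
trading test length against precision (first-N-trials truncation for
Faces, sparser location subsets for Search); normative reference limits
(maximum-likelihood Gaussian/Gamma fits with 99% cutoffs, whole-test and
per-location); the eccentricity power-law fit; and Spearman covariate
associations. Simulated observers and a synthetic two-run cohort
generator (50 search participants, 30 of them with face data) make every
step testable end to end.

## Worked example

```r
library(tabvis)

# one simulated face-test run: 50 trials, reproducible by seed
obs <- observer_model(face_threshold = 3.4)
ses <- run_face_session(obs, n_trials = 50, seed = 42)
ses
#> <face_session: 50 trials, final threshold 3.943 d>

# one search run over all 62 locations
run_search_session(obs, search_grid(), "all", seed = 42)
#> <search_session: 62 locations, median RT 1.782 s>

# a synthetic two-run cohort, analysed at the short protocol
# (first 20 face trials, refined 22-location search subset)
coh <- generate_cohort(n_search = 50, n_faces = 30, seed = 1)
ev <- evaluate_cohort(coh, n_boot = 2000, seed = 2)
ev
#> Psychometric evaluation
#>   Faces  (first 20 trials): CoR95 1.026 d {0.837, 1.354}, 99% cutoff 4.332 d
#>   Search (22 locations)   : CoR95 0.888 s {0.742, 1.137}, 99% cutoff 2.752 s
#>   Eccentricity power law: rt = -3.541 * ecc^-0.3066 + 3.63 (adj R2 0.940)
#>   Faces vs search: rho = -0.014 (p = 0.941, n = 30)
#>   Usability: faces 9.61 / 10, search 9.69 / 10
```

Reading the output: the CoR95 values say that 95% of test-retest
differences fall within ±1.03 d (Faces) and ±0.89 s (Search) under the
simulated observers' noise; the braces are BCa confidence intervals. The
99% cutoffs are the scores below which 99% of the fitted healthy
population falls — higher scores flag possible abnormality
(`classify_score()`). The power law summarises how per-location median
RT grows away from fixation. See `vignette("tabvis-methods")`
(`vignettes/tabvis-methods.Rmd`) for the models, parameter choices, and
what the synthetic cohort does and does not emulate — in particular why
the simulated Faces CoR95 is larger than a deployed test's.

Small bundled examples live in `inst/extdata/` (a synthetic participant
table with its column-role map, and two toy landmark faces); a thin CLI
over the same functions is in `inst/cli/tabvis.R`.

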