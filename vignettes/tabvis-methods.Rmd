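---
title: "Models and methods behind the tabvis engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the tabvis engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabvis)
```

tabvis re-implements, as headless and fully seedable engines, two
tablet-style tests of real-world visual function — a face-discrimination
threshold test and a visual-search response-time test — together with the
psychometric evaluation pipeline used to characterise such tests:
test-retest repeatability, test-length refinement, and normative limits.
This vignette is the package's own account of the underlying models, the
parameters that matter, and the design choices that were genuinely open.

## The face-discrimination test

The test is a four-alternative forced choice ("spot the odd one out"):
three identical standard faces and one target face differing along a
dissimilarity axis *d*. Faces are represented by 127 planar landmark
points; *d* is the Euclidean distance between the stacked landmark vectors
of the standard and target (`face_dissimilarity()`), and
`morph_face()` moves a face linearly along the (face − reference)
direction so that dissimilarity grows linearly with the morph percentage.
Only the landmark arithmetic is implemented — no image warping or
rendering.

Difficulty is driven by a Bayesian adaptive (QUEST-family) staircase over
a discretised threshold domain. The assumed psychometric function is a
Weibull:

$$p(\text{correct} \mid x, t) \;=\; \gamma + (1 - \gamma - \delta)
\left(1 - e^{-(x/t)^{\beta}}\right)$$

with guess rate $\gamma = 0.25$ (forced by the four alternatives), slope
$\beta = 3.5$ and lapse rate $\delta = 0.01$ — the conventional defaults
of the adaptive-psychophysics literature, all exposed through
`psychometric_params()`. After each response the posterior over candidate
thresholds is multiplied by the likelihood of that response and
renormalised (`quest_update()`); the outcome measure is the posterior
mean (`threshold_estimate()`), recomputed after every trial so that
shorter tests can be emulated post hoc by truncation. The next stimulus is
placed at the current posterior mean (`next_level()`), matching the
estimator; the deployed protocol runs 50 trials.

Numerical choices: the domain is $d \in [0.5, 8]$ in 301 evenly spaced
points (grain 0.025 d), bracketing with wide margin the 3–4 d band
typical of normally sighted young adults; the prior is a Gaussian (mean
3.5 d, sd 2.0 d) truncated to the domain. The staircase operates in
linear d-units, the scale on which thresholds are reported. A zero total
likelihood (possible only with numerically degenerate inputs) raises an
error rather than silently renormalising.

A property worth knowing: posterior-*mean* threshold estimates under a
4AFC likelihood carry a small positive finite-sample bias, because the
likelihood of very large candidate thresholds never falls below the
guessing floor. With the defaults above the median recovered threshold
sits about +0.04 d above the true value after 50 trials (about 1.6
domain grains), shrinking to under +0.01 d by 150 trials. The test suite
asserts consistency and a bias bound of 0.1 d rather than bias-freeness.

## The visual-search test

Sixty-three images tile a 26 cm × 17.3 cm landscape screen in a 9-column
× 7-row grid; the centre cell holds the reference image and is never a
target, leaving 62 schedulable locations. Cell centres are converted to
degrees of visual angle at a 50 cm viewing distance,
$\mathrm{ecc} = \arctan(r / 50\,\mathrm{cm})$, giving targets between
3.3° (inner ring) and 15.4° (corners). Each run presents every scheduled
location exactly once in seeded random order (`schedule_locations()`);
one response time is recorded per location and the run is summarised by
the median RT (even counts average the central pair).

The refined 22-location protocol is a centre-symmetric layout spanning
all eccentricity bands (4 inner, 8 mid, 10 outer). The deployed test's
exact 22-point membership was published only graphically, so this layout
is a documented reconstruction — flagged non-canonical and overridable by
passing any location vector.

## Simulated observers and the synthetic cohort

`observer_model()` is the generative stand-in for a participant. Its
search side follows a power-law mean RT against eccentricity,

$$\mathrm{RT}(\mathrm{ecc}) = a\,\mathrm{ecc}^{\,b} + c,$$

defaulting to the field fit for normally sighted young adults
($a = -13.14$, $b = -0.05$, $c = 13.56$; seconds), with multiplicative
lognormal trial noise so draws are positive and right-skewed and the
median stays on the mean curve. Eccentricities below 1° are clamped
before exponentiation: no real target lies that close to fixation, and
the default curve crosses zero just above 0.5°, so the clamp only guards
misuse. Its face side is a true threshold plus the Weibull above; a
deterministic shim (correct iff level ≥ threshold) supports convergence
checks.

`generate_cohort()` emulates the asymmetric two-run study design the
analysis pipeline expects: 50 participants perform the search test twice
over all 62 locations, and the first 30 also perform the face test twice
at 50 trials per run. Population choices, made once:

* true face thresholds are Gaussian with mean 3.25 d and sd 0.15 d,
  inside the 3–4 d band, with between-run jitter sd 0.05 d;
* participant search speed is a lognormal multiplicative factor
  (log-sd 0.2) on the power-law curve, yielding right-skewed,
  Gamma-compatible median RTs; per-location noise has log-sd 0.45 and
  between-run speed jitter log-sd 0.15, calibrated so that simulated
  test-retest repeatability lands in the regime reported for such tests
  (the within-participant noise magnitude is not itself an established
  quantity);
* covariates (logMAR acuity, logCS contrast sensitivity, digit span,
  0–10 usability ratings) are drawn independently of performance by
  default, reflecting the null associations expected in a homogeneous
  normally sighted cohort; a correlation knob exists for power studies.

What the generator does *not* emulate: learning or fatigue across runs,
process-of-elimination strategies across trials, attention lapses
clustered in time, heavy-tailed RT outliers from touch errors, and any
age or disease effects. Passing tests therefore certify the engines and
the analysis pipeline, not the behaviour of real patients.

Because the simulated face observer responds through the conventional
$\beta = 3.5$ Weibull, its 20-trial threshold estimates are noisier than
those of the deployed test (whose effective slope on this d-axis is
evidently steeper): the simulated faces CoR95 comes out near 1 d rather
than a few tenths. The search side, whose noise is calibrated directly,
reproduces the sub-second CoR95 regime. Both are reported as computed.

## The evaluation pipeline

`bland_altman()` computes bias (run 2 − run 1; the sign convention is a
choice), the sd of paired differences (n − 1 denominator), 95% limits of
agreement, and the 95% Coefficient of Repeatability CoR95 = 1.96 × sd of
differences. The alternative √2-inflated within-subject-sd estimator is
deliberately not the default. Confidence intervals come from
`bca_ci()`: a bias-corrected and accelerated bootstrap (default 20 000
resamples) resampling participants (pairs), never individual runs, so
pairing is preserved. z0 uses the fraction of the bootstrap distribution
below the point estimate with midpoint handling of ties; acceleration
comes from leave-one-out jackknife skewness; endpoints interpolate order
statistics on the normal-quantile scale. Degenerate (all-equal) bootstrap
distributions return a point-mass interval with a warning. At n = 30 the
interval's true coverage at nominal 95% measures about 93.5–94% — the
well-known small-sample undercoverage of BCa — so coverage checks need a
few thousand replications before their Monte-Carlo error is small
against that margin.

Refinement curves re-analyse the same sessions at reduced length:
`faces_refinement()` truncates each run to its first N trials (possible
because the staircase re-estimates after every trial);
`search_refinement()` recomputes medians over sparser location subsets.
The built-in ladder (4, 12, 22, 62) uses *spatially distributed* rungs —
each spans the whole screen — so that rungs differ in sampling density,
not field coverage; a concentric ladder would confound subset size with
eccentricity, and with it the RT magnitude.

`fit_normative()` fits reference distributions by maximum likelihood —
Gaussian for face thresholds (sd uses the n-denominator MLE, documented
because the cutoff is sensitive to the scale estimate) and Gamma for the
positive, right-skewed search medians — and derives the 99% cutoff as
the fitted 0.99 quantile. `combine_runs()` pools the two runs after a
paired-difference gate (t-test by default, Wilcoxon optional) that warns
if the runs differ systematically. `classify_score()` flags scores
strictly above the cutoff; a score exactly at the cutoff is within
norms. By construction about 1% of healthy observers classify outside
their own cohort's cutoff — the suite verifies this calibration at
n = 10 000. `pointwise_norms()` repeats the Gamma construction per
location and `fit_power()` fits the eccentricity power law by
multi-start nonlinear least squares (a deterministic start grid plus 40
seeded random restarts; best SSE wins; adjusted R² with 3 parameters).
`spearman_assoc()` delegates rho and p to the standard rank-correlation
machinery (exact null for n < 20 without ties, t-approximation
otherwise).

## Problem sizes and reproducibility

Every stochastic function takes an integer seed and restores the
caller's RNG state; cohorts derive one named stream per session from the
master seed, so any single session can be regenerated in isolation. The
test suite exercises the pipeline at the study scale (50/30 participants,
two runs), threshold recovery at 200 sessions per true value, BCa
coverage at 4000 replications of n = 30, and calibration at 10 000
draws — sizes at which each check's Monte-Carlo error is small against
the property being asserted. `scripts/acceptance.R` regenerates the
study-scale cohort from a command-line seed and recomputes every
headline quantity from scratch.

## Limitations

The engines are simulation and analysis tools: they contain no stimulus
rendering, no touch input, and no screening-test administration. Norms
built from the synthetic cohort describe the generator, not any human
population; with real session tables in the documented CSV schema, the
same pipeline computes real norms. The face threshold's d-axis is
treated as abstract — how a deployed test maps image manipulations onto
d is outside the package's scope. Only within-visit repeatability is
modelled; between-visit variability, which can include true vision
fluctuation, is explicitly not.
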