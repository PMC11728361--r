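---
title: "Echotexture analysis of muscle ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echotexture analysis of muscle ultrasound: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echotex)
```

## The problem

B-mode ultrasound of spastic muscle (the package's motivating case is the
gastrocnemius medialis after stroke) shows progressive brightening and loss
of fascicular architecture as contractile tissue is replaced by
fibro-adipose tissue. The clinical standard, the modified Heckmatt scale,
compresses this continuum into four visual grades. `echotex` implements a
quantitative pipeline around the coefficient of variation of ROI pixel
intensity — echovariation, `EV = 100 * sd / mean` (percent) — together with
20 companion texture features, an informativeness screen, grade-level
statistics, and a parametric model of the cohort-level EV distribution.

Echovariation is attractive because it is a *relative* measure: a global
gain change multiplies all intensities and cancels in sd/mean, so EV is far
less sensitive to device settings than echointensity (EI, the plain mean).
The package encodes this as a tested invariant: multiplying intensities by a
constant (where exactly representable in 8 bits) leaves EV unchanged while
EI scales proportionally.

## Feature definitions and conventions

All features are computed from the raw 8-bit pixel population of a
rectangular ROI, with no pre-processing. Where a convention is not forced by
the definitions, the package follows the defaults of the scientific-imaging
ecosystem and documents the choice:

* **First-order moments** use divisor *n* (population) — the ROI *is* the
  population, and at typical ROI sizes (10^4 pixels) the n vs n−1
  distinction is negligible. Skewness is Fisher–Pearson g1; kurtosis is
  Fisher excess (normal → 0). For a constant ROI (sd = 0) skew and kurtosis
  are reported as 0 and the result is flagged degenerate; EV of an all-black
  ROI is 0 by the same convention.
* **GLCM** (distance 5 px, angle 0°, 256 levels) counts *ordered* pairs at
  the single offset (0, +5) — non-symmetric, normalised by the pair count.
  Intensities are used directly as levels. Entropy uses the natural
  logarithm over nonzero entries. Correlation of a zero-variance marginal is
  defined as 1 (the degenerate limit of a constant texture). Cluster shade
  and prominence are the Conners moments `sum p * (i + j - mu_i - mu_j)^k`
  with k = 3, 4.
* **GLRLM** quantises to 16 equal-width bins (`floor(g * 16 / 256)`) and
  averages each feature over five scan directions: 0°, 45°, 90°, 135° and
  180°. A 180° scan yields exactly the 0° run set (runs are direction-
  insensitive along a line), so the five-angle average double-weights the
  horizontal direction. This mirrors the five-angle protocol the analysis is
  built to reproduce; `glrlm_features(..., angles = c(0, 45, 90, 135))`
  gives the conventional four-direction average.
* **ROI coordinates** are 0-based and half-open on both axes, so box area is
  `(row_end - row_start) * (col_end - col_start)` with no ±1 bookkeeping.
  ROIs are plain rectangles (no masks). Cohort-table ROIs must have area
  ≥ 64 px — smaller populations make second-order statistics degenerate —
  but `extract_roi()` itself accepts any non-empty box so that small
  examples and tests remain expressible.

Every GLCM and GLRLM feature is verified in the test suite against
independent brute-force oracles (naive pair counting and explicit run
walking) on hundreds of random small images, at 1e−12 (GLCM) or exact
(GLRLM) tolerance.

A caution on shift invariance: variance, SD and GLCM contrast are exactly
invariant under adding a constant to all pixels, but the 16-bin GLRLM
quantisation is not — a shift can merge intensities that straddled a bin
boundary. The invariance holds exactly for shifts aligned to the
quantisation grid (multiples of 16), which is what the suite tests.

## The informativeness screen

For each feature the cohort is ordered from the highest to the lowest value
and the 10 images at each extreme are assessed by two raters for
"more affected" tissue. A feature is informative only when, for *both*
raters, one extreme is unanimously affected (10/10) and the other
unanimously unaffected (0/10). This strict reading — any intermediate count
excludes the feature, as does unanimity at *both* extremes — is the only
operationalisation consistent with the published tally table shipped at
`inst/extdata/rater_assessments.csv`, on which it selects exactly
echointensity (high values affected), echovariation and kurtosis (low
values affected). Ranking ties are broken by ascending image id; with
continuous features ties are rare and the rule only serves determinism.

The packaged rater simulator labels an image "more affected" when its grade
is ≥ 3, with an optional independent label-flip probability. It stands in
for blinded human raters in end-to-end tests; it does not model rater
training or consensus dynamics.

## Statistics

* Pearson correlation (not Spearman) against the grade coded 1–4: treating
  the ordinal grade numerically is what makes the cohort correlation
  reproducible in closed form from per-grade moments (below).
* Strength bands on |r|: ≥ 0.80 very strong; [0.60, 0.80) moderately
  strong; [0.30, 0.60) moderate; < 0.30 weak. The source criteria leave
  (0.50, 0.60) and the boundary points undefined; contiguous half-open
  bands close the gaps.
* Min-max normalisation is provided for comparability of plotted features;
  it is affine and therefore provably (and testedly) irrelevant to Pearson
  correlations. A constant column maps to zeros.
* The grade comparison reports mean ± SD (divisor n−1, the reporting
  convention), an omnibus test, and all six pairwise two-sided rank-sum
  (Wilcoxon/Mann–Whitney) tests with Bonferroni factor m = 6
  (`p_adj = min(1, 6p)`). In `method = "auto"`, Kruskal–Wallis is chosen
  over ANOVA when any group fails Shapiro–Wilk at 0.05 — a computable
  stand-in for judging normality from histograms and Q-Q plots. Rank-sum
  (unpaired) tests are used because the grade groups are independent and of
  unequal size; a paired Wilcoxon is not defensible here.
* `pooled_pearson_from_group_stats()` is the exact closed form for the
  correlation between a group code and a measurement given only group
  sizes, means and SDs (divisor-n): total variance = within + between, and
  the covariance depends only on group means. With the default grade
  profiles (24/58/24/24; 67.28 ± 15.05, 46.62 ± 7.17, 37.16 ± 4.94,
  26.85 ± 4.06) it gives −0.8086 → −0.81 at two decimals. The suite also
  checks it against direct Pearson computation on explicitly constructed
  moment-matched data at 1e−12.

The cohort treats its 130 ROIs as independent although they arise from two
limbs (and multiple images) per subject; the within-subject dependence is
deliberately not modelled — a known limitation of the design being
reproduced, not an oversight.

## The synthetic cohort generator

No clinical images ship with the package; the generator produces graded
speckle cohorts with the statistical structure the analysis assumes, so
every downstream stage is testable end to end.

Per image at grade g:

1. an EV target is drawn from the grade's Normal(ev_mean, ev_sd²)
   truncated to (5, 150)% — the default profiles put grades 2–4 more than
   5 SDs from the bounds, so truncation is effectively inactive there (the
   suite verifies the rejection sampler never rejects at 10^5 draws);
2. a Gaussian random field is smoothed to the speckle correlation length
   (default 2 px), standardised on the log scale to
   `sigma_log = sqrt(log(1 + cv^2))` — the lognormal shape whose CV equals
   the target — and exponentiated, giving unit-scale multiplicative speckle;
3. sinusoidal fascicular striation (default period 16 px) is added with
   amplitude `0.2 * (5 - grade) / 4`: banding is strongest in normal muscle
   and effaced at grade 4;
4. the field is affinely standardised to the exact target moments
   (mean = ei_mean, SD = ei_mean · EV/100), then the standardise-and-clip
   step is iterated so that the *clipped* [0, 255] image still carries the
   exact target moments; the resulting saturation mass at 255 in bright
   high-grade images plays the role of acoustic saturation;
5. the image is rounded to 8 bits. Generation aborts if the target SD
   violates the Bhatia–Davis bound (variance on [0, 255] with mean m cannot
   exceed m(255 − m), applied with a 0.95 safety factor) or if the final
   extracted EV deviates from the target by more than 1.5 percent-points.
   In practice the iteration converges to deviations of order 10^-3.

The per-grade EI means (60, 105, 150, 195) are a modelling choice: the
direction (EI rises with grade) is established, but no per-grade EI values
are published, so the defaults are spaced evenly across the usable 8-bit
range to keep every EV target feasible under the Bhatia–Davis bound while
remaining strictly grade-monotone. Because the moment-preserving clip makes
per-image EI and EV essentially exact, the cohort-level invariants — mean
EI strictly increasing, mean EV strictly decreasing with grade, extracted
EV correlating ≥ 0.99 with its targets — hold by construction and are
tested rather than assumed.

What the generator does *not* emulate: ultrasound point-spread functions,
depth-dependent attenuation and time-gain compensation, fascia echoes, or
any device-specific speckle statistics. Passing tests therefore demonstrate
that the *analysis pipeline* behaves correctly on data with the assumed
statistical structure; they are not evidence about any particular scanner
or patient population.

## The EV distribution model

Sorting a cohort's EV values in descending order and plotting them against
rank x = 1..n (1-based; recorded in the fit object as `x_convention`)
yields a smooth decreasing curve fitted as

    y = a e^(bx) + c e^(dx) + E,   b, d in [-10, 0],  a, c >= 0.

Fitted solutions routinely sit in a degenerate regime: |d| of order 10^-6
with c and E huge and nearly cancelling, i.e. the slow component is
numerically the straight line `c d x + (c + E)`. Two consequences drive the
implementation:

* **Evaluation** uses `a e^(bx) + c expm1(dx) + (c + E)`; the naive form
  loses most significant digits when c ≈ -E ≈ 10^5.
* **Fitting** reparameterises to (a, b, c, d, K = c + E), initialises
  structurally — a linear fit to the tail half gives (d0 = slope/c0,
  K0 = intercept, c0 = 10^5); a log-linear fit to the head residuals gives
  (a0, b0) — and runs 20 bounded Levenberg–Marquardt starts with jittered
  (a0, b0) under a fixed internal seed, followed by restart polishing
  (re-running LM from the incumbent resets the damping and keeps descending
  the ill-conditioned valley). Convergence tolerances are set to machine
  level (ftol = ptol = 1e-15) because the stopping criteria, not the
  arithmetic, limit accuracy here.

Acceptance of the fit is in *function space*: on noiseless model-generated
data the fitted curve reproduces the inputs to RMS below 1e-6 (the suite
observes machine-precision recovery), while the individual (c, d, E) values
are not claimed to be identifiable. The fit object carries a
`condition_flag` set when the column-scaled Jacobian's condition number
exceeds 1e8, and no parameter uncertainty intervals are offered — they are
meaningless under the degeneracy. Permuting the input leaves the fit
unchanged (sorting is internal); constant input is rejected (zero total sum
of squares).

## Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate (or load) → extract → select → correlate →
compare → fit, writing a CSV/JSON report bundle plus a manifest recording
the seed. Every random draw flows from the single configured seed: cohort
generation seeds the R RNG once; the rater simulation uses a derived seed;
the curve fit's multi-start jitter uses its own fixed seed and restores the
caller's RNG state. Two runs with the same seed produce byte-identical
feature tables and fit reports, which the suite asserts.

Test problem sizes are chosen to exercise every code path at desk scale:
oracle equivalence on 200 random images up to 16×16; generator calibration
on the default 130-image cohort at 128×128; round-trip checks over 200
images per extreme grade; a 1000-replicate null simulation confirming the
Kruskal–Wallis stage holds its 5% level within ±2 points. The full suite
runs in about a minute.

## Known limitations

* Rectangular ROIs only; no masking, no DICOM, no cine loops.
* The within-subject correlation of multiple images per limb is ignored
  throughout (see above).
* The rater simulator is a threshold-plus-noise caricature of expert
  judgement; no automatic image-quality exclusion rule is provided because
  expert exclusion criteria ("unclear fascia delineation, significant
  artifacts") have no computable definition.
* Speckle realism is limited to "spatially correlated multiplicative noise
  with controllable first-order statistics"; conclusions about physical
  scanners require real images.
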