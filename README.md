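# echotex

Quantitative echotexture analysis of B-mode muscle ultrasound.

Muscle affected by upper-motor-neuron lesions (e.g. post-stroke spasticity)
undergoes atrophy and fibro-adipose replacement, which brightens the
ultrasound image. Clinically this is graded with the modified Heckmatt scale
(1 = normal echotexture, 4 = severely affected) — a coarse, 4-level visual
rating. `echotex` implements a quantitative alternative built around
**echovariation (EV)**, the coefficient of variation of pixel intensity in a
rectangular muscle region of interest (ROI):

    EI = mean(I),    EV = 100 * sd(I) / mean(I)  [%]

where `I` are the 8-bit intensities of the ROI pixel population (population
moments, no pre-processing). Low EV indicates homogeneous, bright,
structure-poor muscle — poorer tissue quality; high EV indicates preserved
heterogeneous architecture.

The package provides:

- **Feature extraction** — the 21 echotexture features of the analysis:
  6 first-order (EI, variance, SD, EV, skew, kurtosis), 10 grey-level
  co-occurrence matrix features (distance 5, angle 0°, 256 levels;
  correlation, dissimilarity, contrast, homogeneity, ASM, energy, max
  probability, entropy, cluster shade, cluster prominence) and 5 run-length
  matrix features (16 grey levels, averaged over the 0°/45°/90°/135°/180°
  directions; SRE, LRE, GLU, RLU, RPC).
- **Informativeness screening** — rank images per feature, take the top-10
  and bottom-10, tally two raters' "more affected" judgements, and keep only
  features whose extremes correspond 100% with impairment in opposite
  directions for both raters.
- **Statistics** — min-max normalisation, Pearson correlation with strength
  bands (|r| ≥ 0.80 very strong, 0.60–0.80 moderately strong, 0.30–0.60
  moderate, < 0.30 weak), Kruskal–Wallis/ANOVA grade comparison with
  Bonferroni-corrected pairwise rank-sum tests, and an exact closed-form
  pooled Pearson correlation from per-group summary moments alone.
- **EV distribution model** — sort the cohort's EV values in descending
  order and fit `y = a·e^(bx) + c·e^(dx) + E` (x = image rank) by bounded
  multi-start Levenberg–Marquardt, returning a classed model object with
  `print`, `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot`
  methods.
- **Synthetic cohorts** — a seeded generator of graded speckle images whose
  per-grade EV distributions follow N(67.28, 15.05²), N(46.62, 7.17²),
  N(37.16, 4.94²), N(26.85, 4.06²) for grades 1–4 with group sizes
  24/58/24/24, so the full pipeline is testable without clinical images.

## Worked example

```r
library(echotex)

res <- run_pipeline(pipeline_config(seed = 42, out_dir = "run42"))
#> [echotex] simulate: generating seeded cohort (seed 42)
#> [echotex] extract: 130 images x 21 features
#> [echotex] select: two-rater extreme-image screen (k = 10)
#> ...

res$selection$direction[c("echointensity", "echovariation")]
#>          echointensity          echovariation
#> "high_values_affected"  "low_values_affected"

cor(res$features$echovariation, res$features$grade)
#> [1] -0.80232

res$fit
#> Sorted-EV distribution model: y = a*exp(b*x) + c*exp(d*x) + E
#>   n = 130 images (x = rank 1..130, descending EV)
#>       a       b       c       d       E
#> ...
#>   R-squared: 0.9943
```

High EI sits at the "more affected" extreme and low EV at the "more
affected" extreme for both simulated raters, reproducing the expected
clinical directionality; EV correlates strongly and negatively with the
impairment grade (−0.80, "very strong"); and the sorted EV distribution is
captured by the double-exponential-plus-offset model with R² ≈ 0.994. The
`run42/` directory holds the report bundle (feature table, selection,
correlation tables, group comparison, fit report, manifest).

For image data on disk, use `pipeline_config(mode = "image_dir",
image_dir = ...)` with a `cohort.csv` of ROI boxes and grades; see
`?load_cohort_table`. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

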