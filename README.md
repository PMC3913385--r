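# plaquantify

Quantifies dental plaque from intraoral quantitative light-induced
fluorescence (QLF) images and runs the case-control statistics that
relate plaque burden to pregnancy risk status.

Under violet light, sound enamel fluoresces green while bacterial
porphyrins in mature plaque — and dye-disclosed plaque generally —
fluoresce red, so plaque status lives in the red/green contrast of an
8-bit RGB image. The package implements:

* **Plaque coverage (%)** on disclosed images: deinterlace, split
  channels, integer-divide red by green (floor division, so value ≥ 1 ⇔
  R ≥ G), classify ratio 0 as plaque-free and ≥ 1 as plaque-covered,
  and report the plaque share of pixels inside a polygon tooth ROI:

  coverage = 100 · |{p ∈ ROI : ⌊R(p)/G(p)⌋ ≥ 1}| / |ROI|

* **Red-fluorescence elevation (ΔR%)** on undisclosed images: with
  per-pixel ratio r = R/G and r₀ the mean ratio over a plaque-free
  reference ellipse, ΔR(p) = 100·(r(p) − r₀)/r₀; pixels with
  ΔR ≥ 20% (configurable) are detected as red-fluorescent and ΔR% is
  their mean elevation.

* **Cohort layer**: per-subject means over 10–12 anterior teeth
  (FDI 13–23, 33–43), ordered exclusion rules (first visit only,
  ≥ 10 natural anterior teeth, no recent antibiotics, complete
  covariates) with a full exclusion log, and delivery-outcome binning
  (< 28 / 28–34 / 34–37 / ≥ 37 weeks).

* **Statistics**: pooled two-sample t-tests (from raw data or published
  mean/sd/n summaries), Pearson chi-squared without continuity
  correction, Pearson correlation, and multiple logistic regression of
  case/control status on coverage, ΔR%, smoking, BMI and maternal age,
  with Wald odds ratios OR = exp(β) and 95% CIs exp(β ± 1.96·SE).

* **Synthetic data**: tooth-image and cohort generators with known
  ground truth (plaque masks, generating coefficients, a configured
  coverage–ΔR% correlation of 0.55), so the whole pipeline is testable
  without clinical data.

## Worked example

```r
library(plaquantify)

# a 512x512 synthetic tooth: 25% plaque band, noise, interlacing
sim <- simulate_tooth_image(width = 512, height = 512,
                            plaque_fraction = 0.25, noise_sd = 4,
                            interlace_amplitude = 20, seed = 1)
coverage(sim$image, sim$roi)$coverage_pct
#> [1] 24.976

# undisclosed-style image generated at a 70% red-fluorescence elevation
und <- simulate_tooth_image(width = 512, height = 512,
                            plaque_fraction = 0.25, delta_r_target = 70,
                            seed = 1)
delta_r(und$image, und$roi, und$reference)$delta_r_pct
#> [1] 70

# a simulated 91-subject case-control cohort through the analysis layer
cohort <- simulate_cohort(seed = 1)
s <- summarize_subjects(cohort$cohort, cohort$measurements)
build_table2(s)$table
#>               term   beta std_error wald_p odds_ratio ci_lower ci_upper
#> 1  plaque_coverage  0.043     0.019  0.028      1.043    1.004    1.084
#> 2 red_fluorescence -0.006     0.016  0.712      0.994    0.963    1.026
#> 3          smoking  0.269     0.254  0.288      1.309    0.796    2.154
#> 4              bmi  0.031     0.041  0.459      1.031    0.951    1.118
#> 5     maternal_age -0.029     0.046  0.525      0.971    0.888    1.062
```

The measured coverage (24.98%) recovers the generated 25% plaque
fraction to within rasterization error despite noise and interlacing;
the ΔR% measurement recovers the generated elevation exactly on a clean
image. In the simulated cohort the logistic table reads as usual: each
row is a predictor's per-unit log-odds coefficient for case status with
its Wald standard error, p-value and odds ratio — here coverage carries
a significant positive association (OR 1.043 per percentage point,
95% CI 1.004–1.084) while the other predictors are null, reflecting the
draw's generating structure rather than any clinical claim.
`build_table1(s)` produces the companion case-vs-control
characteristics table, and
`pearson_r(s$mean_coverage_pct, s$mean_delta_r_pct)` the coverage–ΔR%
correlation (r = 0.388 on this draw).

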