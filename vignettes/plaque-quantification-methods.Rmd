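---
title: "Methods: QLF plaque quantification and case-control analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QLF plaque quantification and case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquantify)
```

## The measurement problem

Under violet illumination, sound tooth enamel fluoresces green while
bacterial porphyrins in mature dental plaque fluoresce red; a disclosing
dye strengthens the red signal of all plaque. Quantitative light-induced
fluorescence (QLF) imaging therefore encodes plaque status in the
red/green contrast of an ordinary 8-bit RGB intraoral image. This
package implements two planimetric measures on such images and the
case-control statistics used to relate them to pregnancy risk status:

* **Plaque coverage (%)** — the fraction of a tooth's visible surface
  classified as plaque-covered, measured on disclosed images.
* **Red-fluorescence elevation (ΔR%)** — the mean percentage elevation
  of the red/green ratio over a plaque-free reference region of the same
  tooth, measured on undisclosed images.

## Plaque coverage by channel-ratio thresholding

For each tooth, an analyst supplies a polygon region of interest (ROI)
around the tooth boundary. The image is split into its 8-bit channels
and the red channel is divided pixel-wise by the green channel in
integer arithmetic. Because enamel is green-dominant and disclosed
plaque red-dominant, the result is an almost entirely black image with
values 0, 1, 2, occasionally 3: value 0 is read as plaque-free and any
value ≥ 1 as plaque-covered. Coverage is the plaque-covered share of
pixels inside the ROI, from a histogram count.

Numerical choices, all configurable:

* **Division rounding.** The default is floor (truncating) division, so
  "plaque" at threshold 1 means exactly R ≥ G — the natural biological
  reading, and consistent with the observed value set {0, 1, 2, 3}.
  Half-up rounding is available (`rounding = "round"`) for sensitivity
  analysis; it shifts the effective boundary to R ≥ G/2.
* **Zero green.** `G = 0, R > 0` maps to 255 (a red signal with no green
  is maximally plaque-like); `R = G = 0` maps to 0 (a dark pixel carries
  no evidence).
* **Rasterization.** A pixel belongs to a ROI exactly when its centre
  lies strictly inside the polygon under the even-odd rule (centres on
  an edge are excluded). Pixel (row *i*, col *j*), both zero-based,
  occupies \[*j*, *j*+1) × \[*i*, *i*+1) with centre
  (*j*+0.5, *i*+0.5), origin top-left. This makes pixel counts exact
  for integer-aligned rectangles and fully oracle-checkable.
* **Deinterlacing.** Video capture can leave horizontal interlacing
  artifacts, so by default each image is deinterlaced before the ratio:
  every scan line of one field parity (zero-based odd rows by default)
  is replaced, per channel, by the rounded (half-up) mean of its two
  vertical neighbours; boundary rows of that parity are copied from
  their single neighbour. This is the simplest artifact-removing filter
  consistent with neighbour-consistency of the other field; it is a
  design choice of this package, not a claim about any particular
  historical plugin. One consequence worth knowing: isolated one-pixel
  features on the replaced field do not survive the filter, so scattered
  single-pixel plaque should be measured with
  `deinterlace_first = FALSE`.

## Red-fluorescence elevation (ΔR%)

The analyst additionally supplies an elliptical reference region on
plaque-free enamel of the same tooth. With real-valued per-pixel ratio
r = R/G and reference ratio r₀ (the mean of r over the reference mask),
each ROI pixel's elevation is ΔR = 100·(r − r₀)/r₀. Pixels with ΔR at
or above a detection threshold (default 20%) count as red-fluorescent;
`delta_r_pct` is the mean elevation over those detected pixels, and the
red-fluorescent area is the detected pixel count (times mm²/pixel when
calibrated). Pixels with G = 0 are excluded throughout, as their ratio
is undefined.

The historical instrument computed ΔR% in closed proprietary software;
no formula is published. The ratio-based, detected-pixel-mean definition
above is this package's own convention, chosen because it is invariant
to global illumination rescaling (a pure ratio) and produces values on
the scale reported for anterior teeth in pregnancy cohorts (ΔR% ≈
60–70). Whether a proprietary implementation averaged over detected
pixels, the whole ROI, or reported a maximum is unknowable from the
outside; the detected-pixel mean was chosen as the only variant whose
null case (no detection) is well defined without a zero-division rule.
Consequently ΔR% values from this package should be compared within the
package, not byte-matched against other software.

## Subject-level aggregation and exclusions

Each subject contributes up to 12 anterior teeth (FDI 13–23 and 33–43);
the subject's value is the arithmetic mean over measured teeth. The
exclusion filter drops, in order: repeat visits (only the first imaging
visit counts, to avoid observation-induced improvements in oral
hygiene), subjects with fewer than 10 natural anterior teeth, recent
antibiotic users, subjects missing BMI/smoking/age, and withdrawals.
Each row is logged once under its first matching rule, so the ordering
affects the log but not the retained set, and retained + excluded always
equals the input count. The threshold of 10 teeth is inclusive.
Delivery outcomes are binned half-open: < 28 weeks extreme, \[28, 34)
moderate, \[34, 37) mild, ≥ 37 term; a missing outcome is tabulated as
unknown and excluded from outcome tables.

## The statistical battery

* **Two-sample t-test**: Student's pooled-variance form, two-sided,
  accepting either raw samples or published mean/sd/n summaries. The
  pooled (rather than Welch) form is the default because, applied to the
  published group summaries this package is designed to re-analyse, it
  reproduces the printed p-values to within one unit in the third
  decimal; Welch does not.
* **Chi-squared**: Pearson's test without continuity correction —
  again the variant that reproduces the printed categorical p-values.
* **Pearson correlation** between subject-level coverage and ΔR%.
* **Multiple logistic regression** of case/control status on coverage,
  ΔR%, smoking, pre-pregnancy BMI and maternal age, fit by binomial
  IRLS (`stats::glm`) with a log-likelihood convergence tolerance of
  1e-8 and at most 100 iterations. Wald standard errors come from the
  inverse observed information; odds ratios are exp(β) with 95% CIs
  exp(β ± 1.96·SE) — the fixed 1.96 normal multiplier matching the
  conventional "95% CI for OR" presentation. Complete separation is
  reported as an error naming the worst-offending predictor rather than
  returning unstable estimates.
* **Smoking encoding**: ordinal 0/1/2
  (nonsmoker/stopped-during-pregnancy/smoker-during-pregnancy) by
  default, giving smoking one degree of freedom as in single-row
  presentations of such models; a binary any-smoking encoding is
  available. The coefficients reported are per-unit (unstandardised)
  log-odds; odds ratios printed alongside β values in the motivating
  literature are consistent with per-unit coefficients even where the
  text calls them standardised.
* **Relative group difference** is computed against the larger of the
  two group means, the convention that reproduces both published
  headline percentages (19.29% for coverage, 5.39% for ΔR%).

## What the synthetic generators emulate

**Images.** `simulate_tooth_image()` renders an elliptical tooth
(semi-axes 0.38·W, 0.44·H) of uniform enamel (green 200, R/G = 0.6)
with a contiguous plaque band at the gingival (lower) edge — where
plaque actually accrues — occupying a requested fraction *f* of the
tooth area to the nearest scan line; a scattered-speckle mode exists for
robustness testing. Disclosed-style plaque uses green 120 and
R/G = 1.8; undisclosed-style images instead take a `delta_r_target`,
placing the plaque ratio at `r_enamel · (1 + ΔR/100)`. Optional
Gaussian channel noise and an additive odd-row interlacing offset
emulate capture degradations. The exact plaque mask, a 64-vertex
polygonal tooth ROI and a reference ellipse in the enamel zone are
returned, so measured coverage can be compared against ground truth —
agreement is within one percentage point at zero noise on a 512×512
tooth. Not emulated: specular highlights, gingival tissue, tooth
texture and curvature shading, disclosing-dye unevenness, and
inter-tooth shadowing; passing tests show algorithmic correctness on
idealised geometry, not clinical robustness.

**Cohorts.** `simulate_cohort()` draws maternal age, BMI, smoking and
subject-mean coverage from group-specific distributions whose moments
are calibrated to the published cohort summary (51 cases, 40 controls;
e.g. coverage case N(25.50, 17.45²) truncated to \[0, 100\]); ΔR% is
linked linearly to coverage (slope 0.6374, noise sd 13.87, intercept
50.2) so the population correlation is 0.55 given the truncated-mixture
coverage sd of ~14.3. Per-tooth values scatter (sd 8) around the
subject mean over 10–12 teeth. Delivery gestation follows a logistic
model in coverage calibrated to an overall ~19% preterm rate, with
preterm weeks apportioned over the extreme/moderate/mild bins in the
published 2:3:11 proportions. In `assignment = "logistic"` mode,
covariates come from the pooled mixture and case status is a Bernoulli
draw with logistic probability under configurable coefficients
(defaults: intercept −2, coverage −0.042, ΔR% 0.036, smoking −0.822,
BMI 0.005, age 0.030) — the mode used for parameter-recovery and
calibration studies, where the generating coefficients are the
estimands. This calibration makes the generator produce *structurally*
comparable data; it is not a reconstruction of any real subject.

`make_accounting_cohort()` assembles the recruitment-accounting fixture:
109 subjects of whom 7 lack ≥ 10 natural anterior teeth, 5 took
antibiotics, 4 have missing covariates and 2 withdrew, leaving 91
analyzable (51 cases, 40 controls). The 9 analysis-stage exclusions are
apportioned 5 antibiotics / 4 missing covariates; only their total is
externally constrained.

## Verification problem sizes

The package's test suite checks the segmentation path against an
independent brute-force per-pixel oracle on 200 randomized image/ROI
instances up to 64×64; plaque-fraction recovery on 512×512 clean teeth;
logistic coefficient recovery on 200 simulated cohorts of n = 5000
(95% Wald CI covering each generating coefficient in ≥ 93% of fits);
and the type-I error of the coverage Wald test on 1000 null cohorts of
n = 400, which must lie in 5% ± 2%. The null-calibration size of 400 is
a deliberate choice: Wald tests are asymptotic, and no finite-sample
correction is applied, so calibration is checked where the asymptotics
are expected to hold rather than at the study's n = 91, where mild
anti-conservatism is a property of the method class, not of this
implementation. Correlation consistency is judged over 500 simulated
study-sized cohorts (n = 91): the mean sample r must sit within 0.03 of
the 0.55 target, and at least 99% of draws within 0.2 (the sampling sd
of r at this n is ~0.07, so occasional larger excursions are expected
of a correct estimator).

## A worked example

```{r example, eval = FALSE}
sim <- simulate_tooth_image(width = 512, height = 512,
                            plaque_fraction = 0.25, noise_sd = 4,
                            interlace_amplitude = 20, seed = 1)
coverage(sim$image, sim$roi)$coverage_pct      # ~25

cohort <- simulate_cohort(seed = 1)
s <- summarize_subjects(cohort$cohort, cohort$measurements)
build_table1(s)                                # case-vs-control table
build_table2(s)$table                          # logistic ORs with 95% CIs
pearson_r(s$mean_coverage_pct, s$mean_delta_r_pct)
```

## Known limitations

* ΔR% follows this package's explicit convention and will not
  byte-match proprietary implementations.
* The deinterlace filter assumes one field is trustworthy; genuinely
  corrupted even *and* odd fields are not recoverable.
* Physical areas (mm²) require an externally supplied mm-per-pixel
  calibration; none is inferred from the image.
* The logistic model's Wald inference is asymptotic; at n ≈ 91 with
  five predictors, confidence intervals are mildly anti-conservative.
* The synthetic cohort reproduces first and second moments and one
  correlation, not the full joint distribution of real covariates
  (e.g. smoking–BMI dependence is absent).
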