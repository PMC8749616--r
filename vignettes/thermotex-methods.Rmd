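---
title: "Texture analysis of false-color thermograms for equine pregnancy detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis of false-color thermograms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotex)
```

## The problem

Infrared thermography renders the heat emitted by the body surface as a
false-color image. In pregnant mares, growing uterine and fetal tissue
increases local blood flow and metabolic heat production, which changes
both the level and — more robustly — the *texture* of the thermal pattern
over the flank. `thermotex` implements a screening pipeline that asks: of
all combinations of a color component and an image-texture feature, which
ones behave like usable pregnancy indicators, and how accurate is a simple
threshold rule built on them?

The pipeline has five stages:

1. **Color decomposition.** Each 8-bit RGB thermogram is decomposed into
   ten grayscale planes: R, G, B (taken directly), the shared brightness
   plane Y, the YUV chrominance planes U and V, the YIQ chrominance planes
   I and Q, and the HSB hue and saturation planes.
2. **Texture extraction** inside a polygonal flank ROI: 13 first-order
   histogram statistics (HS) and 11 Haralick features computed on both the
   symmetric (GLCM) and asymmetric (GLCH) gray-level co-occurrence matrix,
   horizontal displacement at distance 1 — 35 features x 10 components =
   350 combinations per image.
3. **Criterion 1 — control homogeneity.** A usable indicator must be
   stable in non-pregnant animals: combinations whose non-pregnant series
   differ between imaging sessions (one-way ANOVA, or Kruskal–Wallis when
   any series fails a Shapiro–Wilk gate at α = 0.05) are dropped; the rest
   get a pooled non-pregnant mean ± SD.
4. **Criterion 2 — sustained separation.** The pooled non-pregnant values
   and the eight pregnant month series enter one omnibus model; a
   combination survives if the post-hoc-adjusted non-pregnant-vs-month
   contrast (Tukey or Dunn) is significant from some month through the end
   of pregnancy. After this stage the GLCH set is dropped when it merely
   duplicates the GLCM selections.
5. **Criterion 3 — monotone trend**, then **threshold accuracy**: for each
   surviving combination, thresholds at the pooled mean shifted by 0, 1,
   and 2 SDs classify each animal, giving per-month sensitivity,
   specificity, and predictive values.

## Color transforms

The chrominance planes are integer transforms with an offset
Θ = 2⁸ − 1 = 255 chosen so each formula's range maps exactly onto
[0, 255] (for example the U maximum (886 + 886)·255/1772 = 255). Two
printed sign conventions in circulating versions of these formulas do not
cancel on the gray axis; `thermotex` uses the internally consistent
reading — Q with a positive B coefficient (+3111B), and the H/S chroma
pair u = (886B − 587G − 299R)/886, v = (701R − 587G − 114B)/701 — under
which R = G = B gives exactly U = V = I = Q = 128, S = 0, H = 0, and the
0.937 saturation constant is precisely the normalizer that brings the
maximum-chroma magenta corner to 255. The literal signs remain available
via `color_config(corrected_signs = FALSE)` for comparison. Values are
rounded half away from zero (configurable to floor) and clipped.

## Texture features

All first-order statistics are computed from the normalized histogram of
ROI pixels only; co-occurrence pairs require both endpoints inside the
mask, so pixel counts ("NM" in the usual formulas) always mean the ROI
size. Conventions that the formulas leave open, fixed here and exercised
by the oracle tests:

* **Gray levels** enter the Haralick formulas on their native 0..K−1
  scale (K = 256 by default; reductions are explicit, never silent).
* **Logarithms** in the entropy features are natural; the base is a
  configuration constant.
* **Correlation** uses marginal standard deviations (not variances) in
  the denominator and is defined as 0 when either marginal SD is 0;
  0·log 0 ≡ 0 throughout.
* **Skewness/kurtosis** are the standardized central moments
  (variance^−3/2 and variance^−2), kurtosis excess; both defined as 0 for
  a degenerate histogram.
* **Percentiles** are the printed min-K rule: the smallest level at which
  the cumulative histogram reaches the quantile.
* **Domn/Maxm** windowed peaks: `Domn_r` is the start of the width-r
  window with maximal probability mass (smallest level on ties) and
  `Maxm_r` that mass, r ∈ {1, 10}. The available formulations of these
  features are ambiguous; this sliding-window reading is a documented
  choice, validated only against its own oracle.

For the horizontal offset, every functional that is linear in p with a
symmetric kernel (contrast, homogeneity, the sum/difference family) is
identical between GLCM and GLCH by construction; the test suite asserts
this exactly, mirroring the empirical observation that symmetric and
asymmetric matrices carry the same screening information.

## The selection cascade

Statistical conventions:

* Mares contributing several sessions are treated as independent
  observations per month — the convention the per-month series analysis
  implies. The synthetic generator's random intercepts deliberately
  violate this (see below), which is one reason calibration checks use an
  intercept-free null.
* Criterion 2 defaults to one omnibus model (pooled non-pregnant group
  plus all months) with Tukey- or Dunn-adjusted control-vs-month
  contrasts; a per-month pairwise variant is available via
  `selection_config(c2_method = "pairwise")`. Dunn's test is implemented
  from the standard rank-based z statistic with tie correction and
  Bonferroni adjustment over the eight control contrasts, as no installed
  package provides it.
* "Gradually increasing" (criterion 3) is formalized as: non-decreasing
  per-month means, strictly positive total change, and Spearman rank
  correlation of exactly +1 between mean and month — i.e. strictly
  monotone in practice, with ties disqualifying. This is the strictest
  defensible reading; it makes trend selection conservative.
* No multiplicity correction is applied across the 350 combinations; the
  cascade is a screening device, not a confirmatory analysis.

Because criterion 2 requires an omnibus rejection *and* a sustained
post-hoc-significant contrast, its null selection rate is necessarily
below the nominal α; the calibrated α-level event is the omnibus
rejection itself. The acceptance checks therefore assert the omnibus rate
≈ α and the selection rate below it, rather than pretending the compound
rule has size α.

## Threshold accuracy

For an increasing indicator the three thresholds are pooled mean − k·SD,
k = 0, 1, 2 (mirrored for decreasing ones): relaxing the threshold with k
admits more positives, so sensitivity is non-decreasing and specificity
non-increasing in k — a structural property the suite asserts on every
synthetic evaluation. A value exactly at the threshold counts as
non-pregnant. Ratios 0/0 in predictive values are defined as 1.00 (a
vacuous predictive value from a classifier that never makes that call),
and reported metrics are rounded half away from zero to two decimals.
Prevalence-adjusted predictive values over an assumed pregnancy
proportion are available via `prevalence_adjusted()`.

The package bundles a reference table of two-decimal Se/Sp/PPV/NPV values
for the 13 selected indicator combinations (8 months × 3 thresholds).
Inverting its rounded rates to integer counts (sensitivity over 14
positives, specificity over 13 negatives) and recomputing the predictive
values reproduces 302 of the 312 cells exactly; 9 of the 10 exceptions
are exactly consistent with 13 positives instead (a denominator swap to
the pregnant-subgroup size in the source material), and a single cell
(Q-component variance, month 6, widest threshold) prints NPV = 1.00 where
specificity 0.00 with an imperfect sensitivity forces NPV = 0 under every
integer reading — a typo the validation flags rather than hides.

## The synthetic cohort generator

No raw thermograms are distributed with the study design this package
targets, so `generate_cohort()` produces seeded synthetic cohorts with
the statistical structure the analysis assumes: 14 non-pregnant mares at
4 sessions and two pregnant subgroups of 13 imaged at months {4,6,8,10}
and {5,7,9,11} — 160 frames. Each frame is a temperature field, clipped
to the camera range 10.0–40.0 °C and rendered through a five-point
blue–cyan–green–magenta–red palette (hot regions red, medium-high
magenta, cold blue, matching thermal-camera annotation conventions).

The field model and its defaults:

* **Baseline** 28.0 °C, plus a per-mare Gaussian intercept (SD 0.5 °C) —
  a plain random-intercept model of inter-animal variation — and an
  optional per-session ambient offset (default 0: acquisition indoors).
* **Smooth anatomical noise**: Gaussian-filtered white noise, SD 0.3 °C
  at correlation length 3 px, rescaled to its target SD after filtering.
* **Pregnancy hot spot**: an elliptical Gaussian of amplitude
  0.2·(m − 3) °C (0.2–1.6 °C across months 4–11, the magnitude reported
  for conventional abdominal thermography in late gestation) and radius
  5 + 1.5·(m − 4) px.
* **Progressive heterogeneity**: iid fine-grain noise with SD
  0.3·sqrt(1.8·1.3^(m−4) − 1) °C, chosen so the *total* within-ROI
  temperature variance grows geometrically, about 30% per month. Texture
  entropies respond roughly linearly to log-variance, so a geometric ramp
  produces uniform month-to-month entropy increments; fetal and uterine
  tissue growth in the second half of gestation is itself super-linear,
  which makes the geometric form the natural choice. A linear SD ramp, by
  contrast, yields a concave entropy response whose late increments
  vanish — and would fail the strict criterion-3 monotonicity not because
  the effect is absent but because the trend plateaus.

Two numerical facts shaped the default frame size of 112 × 112 px. First,
the empirical co-occurrence entropy of a K = 256 matrix estimated from N
pairs cannot exceed ln N; with too small an ROI the late-gestation
heterogeneity signal hits this estimation ceiling and the entropy trend
flattens or reverses. Second, per-frame texture statistics computed on a
smooth field with few independent correlation patches are noisy enough to
mask early-month increments. 112 × 112 (≈ 4,600 ROI pixels, ≈ 9,000
symmetric pairs) leaves the month-11 Red-component entropy well below its
ceiling while keeping a 160-frame cohort extractable in seconds.

What the generator does *not* emulate: radiometric properties of any real
camera, anatomy (the ROI is a fixed convex pentagon standing in for the
flank region bounded by the tuber coxae line), coat and weather
covariates, lactation, and within-mare temporal correlation of texture
beyond the shared intercept (exposed as a parameter rather than asserted,
since the study design gives no value for it). Passing recovery tests on
this generator therefore show that the *pipeline* detects the kind of
progressive texture signal the biology implies — not that real mares are
this clean. Under the default conditions, the residual failure rate of
the recovery checks (roughly one cohort in ten) is dominated by
criterion-1 α-level rejections in the non-pregnant group, which is the
cascade's own prescribed type-I behaviour, not a generator artifact.

## Degenerate inputs and tie-breaks

* Constant series: Shapiro–Wilk is undefined, so constant series are
  routed to the nonparametric branch; fully constant comparisons pass
  criterion 1 with SD 0 (flagged) and claim no separation.
* Empty ROI masks, degenerate palettes and temperature ranges, negative
  SDs, and non-finite effect parameters are rejected with messages.
* Histogram peak ties resolve to the smallest gray level; classification
  ties at a threshold resolve to non-pregnant.

## Problem sizes used by the test suite

Unit tests run on 8 × 8 masked planes (oracle comparisons at 4 and 256
gray levels), 64 × 64 frames for cohort-structure checks, and the default
112 × 112 cohort for recovery and calibration: 20 seeded cohorts for
parameter recovery and 3 intercept-free null cohorts (at 64 × 64) for
test-size calibration. These sizes are the package's chosen desk-scale
study conditions; the pipeline itself is size-agnostic.
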