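# thermotex

Texture analysis of false-color thermograms for non-contact pregnancy
detection in mares.

Infrared thermography pictures the heat emitted by the body surface.
During pregnancy, uterine and fetal growth increase blood flow and
metabolic heat production over the flank, changing not just the local
temperature but the *texture* of the thermal pattern. `thermotex`
implements a complete screening pipeline for this signal, aimed at
researchers in veterinary imaging and anyone evaluating texture-based
diagnostics on false-color images:

1. **Color decomposition** — each 8-bit RGB thermogram is split into ten
   grayscale component planes: R, G, B; brightness
   Y = (299R + 587G + 114B)/1000; the YUV chrominance planes
   U = (886B − 587G − 299R + 886Θ)/1772 and
   V = (−114B − 587G + 701R + 701Θ)/1402; the YIQ planes I and Q; and the
   HSB hue and saturation planes (Θ = 255 maps every range onto [0, 255]).
2. **Texture features** inside a polygonal flank ROI — 13 histogram
   statistics (mean, variance, skewness, kurtosis, five percentiles, and
   windowed histogram peaks) and 11 Haralick features (energy, contrast,
   correlation, homogeneity, and the entropy/variance families of the
   sum and difference distributions) on symmetric (GLCM) and asymmetric
   (GLCH) co-occurrence matrices: 35 features × 10 components = 350
   combinations per image.
3. **Three-criterion selection cascade** — (i) stability across sessions
   in non-pregnant animals (ANOVA/Tukey or Kruskal–Wallis/Dunn behind a
   Shapiro–Wilk gate, α = 0.05), (ii) sustained separation of pregnant
   months from the pooled non-pregnant reference, (iii) strictly monotone
   gestational trend.
4. **Threshold diagnostics** — classify each animal against the pooled
   non-pregnant mean shifted by 0, 1, 2 SDs and report sensitivity,
   specificity, PPV and NPV per combination × month × threshold, plus
   prevalence-adjusted predictive values.
5. **Synthetic cohort generator** — seeded, deterministic thermal cohorts
   with the study's longitudinal design (14 non-pregnant mares × 4
   sessions; two pregnant subgroups of 13 imaged at months 4,6,8,10 and
   5,7,9,11 — 160 frames), expressing pregnancy as a month-growing hot
   spot plus geometrically growing fine-scale heterogeneity.

## Worked example

```r
library(thermotex)

coh   <- generate_cohort(cohort_design(seed = 42))   # 160 synthetic frames
feats <- extract_cohort_features(coh)                # 56,000 feature records
sel   <- run_selection(feats)                        # three-criterion cascade
sel$stage_counts[c("enumerated", "after_c1", "after_c2", "final")]
#> $enumerated
#> [1] 350
#> $after_c1
#> [1] 350
#> $after_c2
#> [1] 277
#> $final
#> [1] 143

subset(sel$results, selected & component == "R" & feature == "Entropy")
#>  component approach feature pass_c1 pooled_mean pooled_sd first_sep_month
#>          R     GLCM Entropy    TRUE    5.873154 0.1086403               5
#>  c2_p_omnibus trend selected
#>  9.509093e-29    In     TRUE
```

350 combinations are enumerated; all 350 are stable in the non-pregnant
group for this seed (criterion 1 is an α = 0.05 test, so a handful fall
out on other seeds), 277 separate pregnant from non-pregnant mares
through the end of gestation, and 143 — led by the entropy family of the
Red and I components, which tracks the growing texture heterogeneity —
also trend monotonically. The Red-component co-occurrence entropy
separates the groups from month 5 onward. Its diagnostic accuracy:

```r
acc <- evaluate_accuracy(feats, sel)
subset(acc, component == "R" & feature == "Entropy" & month == 4)
#>  component approach feature month threshold_k threshold TP FP TN FN Se   Sp  PPV NPV
#>          R     GLCM Entropy     4           0  5.873154 13  6  8  0  1 0.57 0.68   1
#>          R     GLCM Entropy     4           1  5.764514 13 10  4  0  1 0.29 0.57   1
#>          R     GLCM Entropy     4           2  5.655874 13 14  0  0  1 0.00 0.48   1
```

Under the default effect model the entropy indicator already catches
every pregnant mare at month 4 (Se = 1.00 at the bare-mean threshold),
while widening the threshold to mean − 2SD trades all specificity away —
the sensitivity/specificity monotonicity in the threshold index that the
test suite asserts on every evaluation.

## Layout

```
R/                      implementation (color models, texture features,
                        selection cascade, accuracy, generator, pipeline)
inst/cli/thermotex      command-line driver (simulate|extract|select|evaluate|all)
inst/extdata/           reference accuracy table and stage counts (CSV)
tests/testthat/         oracle-backed unit and acceptance tests
vignettes/              methods vignette: models, conventions, design choices
scripts/acceptance.R    end-to-end reproduction script
```
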