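# gaitdep

Gait-based depression recognition from 25-joint skeleton time series.

Depression alters how people walk: slower gait, reduced arm swing, a more
slumped head posture, shorter strides. Markerless depth sensors (Kinect v2
class devices) record the 3-D positions of 25 body joints at 30 Hz while a
person walks naturally, which makes gait a cheap, non-intrusive candidate
signal for screening. `gaitdep` implements the full analysis chain from raw
joint trajectories to diagnostic classification, for clinical-biostatistics
and digital-phenotyping work on case/control walking cohorts:

1. **Skeleton I/O** — a documented plain-text CSV/JSON format for
   `T x 25 x 3` joint-position recordings, with validation.
2. **Synthetic cohorts** — a generator producing labeled case/control
   walking cohorts (defaults: 126 cases, 121 controls, 2 min back-and-forth
   on a 6 m path at 30 Hz). Group-level kinematic means and SDs encode the
   published summary statistics of a clinical depression gait cohort, so
   every downstream stage is testable although clinical recordings of this
   kind cannot be shared.
3. **Preprocessing** — spine-origin coordinate transform
   (`x'_j(t) = x_j(t) - x_spine(t)`), splitting into face-toward /
   back-toward walking passes by the sign of the smoothed spine-Z velocity,
   selection of the middle face-toward pass, left-toe toe-off detection,
   and extraction of a two-gait-cycle segment; all channels are low-pass
   filtered by convolution with the binomial Gaussian kernel
   `g = (1/16)[1, 4, 6, 4, 1]`.
4. **Feature banks** — 10 spatiotemporal features (body sway, left/right arm
   swing, vertical head movement, head posture angle, left/right stride,
   left/right toe clearance, walking speed); 300 time-domain features
   (mean, SD, skewness, kurtosis of each of the 75 channels); 825
   frequency-domain features per the DFT
   `F_k = sum_j x_j e^{-i 2 pi k j / n}` (DC component plus mean, variance,
   SD, skewness, kurtosis of the amplitudes and of the phases per channel).
5. **Inference** — pooled two-sample t summary tables; PCA at 95 %
   cumulative explained variance for the high-dimensional banks; stepwise
   forward logistic regression (likelihood-ratio entry at alpha = 0.05)
   reporting beta, SE, Wald, odds ratios `OR = exp(beta)`, Holm-corrected
   p-values, and Nagelkerke's pseudo-R²
   `R² = [1 - exp(2(l0 - l1)/n)] / [1 - exp(2 l0 / n)]`;
   PC-feature Pearson correlation tables.
6. **Classification** — linear-kernel SVM with stratified 10-fold
   cross-validation (per-fold standardization), sensitivity / specificity /
   AUC for all seven combinations of the three feature banks under
   identical folds, sequential backward selection (SBS), and ROC curves.

## Worked example

```r
library(gaitdep)

cfg <- run_config(cohort = cohort_config(n_case = 30, n_control = 30,
                                         duration = 60, seed = 42), k = 5)
bundle <- run_analysis(cfg)

summary(bundle$cohort$segment_durations)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    1.80    2.20    2.37    2.37    2.54    3.17

subset(bundle$group_table, abs(t) > 2,
       c(feature, case_mean, control_mean, t, p))
#>          feature case_mean control_mean     t       p
#> 2 arm_swing_left     0.243        0.326 -2.87 0.00568

bundle$classification_table
#>                combination sensitivity specificity  auc
#> 1           spatiotemporal        0.67        0.63 0.70
#> 2                     time        0.73        0.90 0.92
#> 3                frequency        0.53        0.73 0.74
#> 4      spatiotemporal+time        0.73        0.73 0.84
#> 5 spatiotemporal+frequency        0.67        0.67 0.68
#> 6           time+frequency        0.73        0.83 0.92
#> 7                      all        0.63        0.80 0.83
```

The two-cycle segments center on ~2.4 s, matching the observed range of
natural gait cycles. The group table flags reduced left-arm swing among
cases (t = -2.87 on this small cohort). The classification table gives the
cross-validated performance of each feature-bank combination; on full-size
cohorts (247 participants, 2-minute recordings — see
`analysis/01_simulate_cohort.R` through `05_report_figures.R`) the
signal-domain banks clearly dominate the stride-level summaries and the
combined time+frequency model is at least as good as either alone.

## Analysis scripts

`analysis/` holds the numbered drivers for the full study pipeline; each is
a thin narrative wrapper over the package functions and writes its tables
under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess_and_features.R
Rscript analysis/03_logistic_inference.R
Rscript analysis/04_classification.R
Rscript analysis/05_report_figures.R
```

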