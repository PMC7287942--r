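# kinemarker

Movement biomarkers for ASD/TD classification from depth-camera skeleton
pose streams.

Children on the autism spectrum show elevated stereotyped and repetitive
movement. Given per-frame 25-joint pose streams (BODY_25 layout: image
coordinates, depth, and a detection confidence per joint) recorded during a
structured session of three stimulus conditions — visual (V),
visual–auditory (VA), visual–auditory–olfactory (VAO), each preceded by a
baseline — kinemarker quantifies per-joint movement, tests group
differences joint by joint, and evaluates how well movement alone
discriminates ASD from typically developing (TD) children.

The package is for researchers in digital behavioural phenotyping who want
this analysis as tested, reusable, fully seeded code rather than a
one-off script — and, because clinical recordings of this kind are not
shareable, it ships a synthetic cohort generator with closed-form movement
structure so every stage can be validated end to end.

## The method

**Features.** Joints are back-projected to camera-frame 3D through the
pinhole model `X = (u − cx)·z/fx`, `Y = (v − cy)·z/fy`, `Z = z`. Within
each session segment, samples with confidence < 0.5 are discarded, and a
joint's movement is the mean Euclidean displacement `‖Δp‖₂` between 3D
positions at adjacent retained frames (gaps are never bridged). This gives
a subjects × (joint, segment) feature table in meters per frame-step.

**Joint statistics.** Each joint × segment cell is screened with
Shapiro–Wilk and compared between groups with the two-sample Wilcoxon
rank-sum test (exact for small tie-free samples), with `*`/`**`/`***`
tiers at p < 0.05 / 0.01 / 0.001.

**Classification.** For each of 24 models ({head, trunk, arms, legs, feet,
all} × {V, VA, VAO, all}): PCA to 95% explained variance, then
leave-one-subject-out (LOSO) cross-validation with per-fold median/MAD
normalization (held-out subject normalized by training statistics), a
Gaussian C-SVM searched over a 7 × 7 cost × gamma grid log-spaced on
[0.1, 1000], and nonlinear SVM-RFE feature ranking with correlation-bias
reduction, driven by the dual-objective change
`DJ(i) = ½αᵀHα − ½αᵀH₍₋ᵢ₎α`. Per-fold ranks are aggregated by median; the
top-k subset and grid point with the best Cohen's kappa
`(p_o − p_e)/(1 − p_e)` is reported, with deterministic tie-breaking.

## Worked example

Simulate a 47-subject cohort (22 ASD / 25 TD) with a strong planted head
effect (ASD head-joint step SD tripled during stimuli), build head
features, and fit the LOSO stack:

```r
library(kinemarker)

cfg <- cohort_config(schedule = segment_schedule(duration_factor = 0.1),
                     effect_map = effect_preset("reported"), seed = 42)
cohort <- generate_cohort(cfg)

features <- build_feature_table(cohort, joints = "head",
                                segments = c("V", "VA", "VAO"))
features
#> Feature table: 47 subjects (22 ASD / 25 TD) x 12 features (4 joints x 3 segments)
#> Mean displacement (m/frame-step), confidence >= 0.50; 0 cell(s) imputed

fit <- loso_svm(features, classifier_config(seed = 7))
fit
#> LOSO-validated Gaussian C-SVM (ASD vs TD)
#>   subjects: 22 ASD / 25 TD; PCA components: 1; selected features: 1/1
#>   chosen cost = 0.1, gamma = 0.1
#>   accuracy 100.00%  TPR 100.00%  TNR 100.00%  kappa 1.00
```

The twelve head features collapse onto one principal component (the
planted effect dominates), one selected feature separates the groups in
every fold, and the LOSO confusion matrix is perfect — kappa 1.00 means
full chance-corrected agreement. The per-joint statistics localize the
effect:

```r
joint_group_tests(build_feature_table(cohort, joints = "head", segments = "V"))
#>   joint segment median_asd median_td        p tier direction
#> 1    15       V     0.0151   0.00471 4.85e-09  ***    ASD>TD
#> 2    16       V     0.0149   0.00475 4.85e-09  ***    ASD>TD
#> 3    17       V     0.0149   0.00481 4.85e-09  ***    ASD>TD
#> 4    18       V     0.0148   0.00472 4.85e-09  ***    ASD>TD
```

Medians sit at the chi-3 closed form `1.5958 × step SD` (0.0048 m for TD
at 3 mm, three times that for ASD). `run_study(study_manifest(cohort = cfg))`
fits all 24 models and returns the 6 × 4 accuracy matrix plus a per-model
detail table (accuracy, TPR, TNR, kappa, selected/total features).

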