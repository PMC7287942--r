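---
title: "Movement biomarkers from skeleton pose streams: model, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement biomarkers from skeleton pose streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinemarker)
```

## The problem

Elevated stereotyped and repetitive movement is one of the more tractable
behavioural markers separating children on the autism spectrum (ASD) from
typically developing (TD) children. kinemarker implements a complete,
testable version of a depth-camera movement-biomarker analysis: a 25-joint
skeleton (BODY_25 layout) is tracked through a structured session of three
stimulus conditions — visual (V), visual–auditory (VA), and
visual–auditory–olfactory (VAO), each preceded by a 2-minute baseline — and
per-joint movement is summarized, compared between groups, and fed to a
supervised classifier evaluated by leave-one-subject-out (LOSO)
cross-validation.

The package has five cooperating parts: pose-stream I/O and segmentation,
a synthetic cohort generator, movement feature extraction, per-joint group
statistics, and the LOSO SVM stack. The study runner combines them into the
6 joint-set × 4 stimulus-set model grid (head, trunk, arms, legs, feet, and
the whole body, crossed with V, VA, VAO, and all three together).

## From pixels to features

Each frame carries, per joint, image coordinates $(u, v)$, a depth $z$ in
meters, and a detection confidence $c \in [0, 1]$. Joints are back-projected
to camera-frame 3D through the pinhole model
$X = (u - c_x)\,z / f_x$, $Y = (v - c_y)\,z / f_y$, $Z = z$. The camera
intrinsics only matter for geometric consistency between simulation and
back-projection; they cancel out of any analysis run end-to-end through the
package. Defaults ($f_x = f_y = 600$, $c_x = 424$, $c_y = 240$) describe a
plausible RGB-D sensor at 848×480.

Frames are assigned to session segments by the half-open convention
$[\mathrm{start}, \mathrm{end})$, so a frame on a boundary belongs to
exactly one segment. Samples with confidence **strictly below** 0.5 are
discarded; a sample at exactly 0.5 is kept. Movement of a joint within a
segment is the mean Euclidean displacement between 3D positions at
*adjacent* original frames. Two design points matter here:

- **Gaps are never bridged.** If confidence filtering removes frame $t$,
  the pair $(t-1, t+1)$ produces no displacement. Bridging would fabricate
  a large distance out of a tracking failure and inflate movement exactly
  where tracking is worst.
- **Units are meters per frame-step**, with no frame-rate normalization by
  default. A `rate` flag is not provided because all recordings in a cohort
  share one frame rate; converting to m/s would rescale every feature by
  the same constant, which the classifier's normalization absorbs anyway.

Cells with no surviving displacement pair are imputed with the column
median, consistent with the pipeline's median-based normalization; the
imputation count is kept on the feature table.

Whether the published 24-model analysis included baseline segments among
the features cannot be determined from the reported feature counts; both
options are supported through `segments`, and the default is stimulus-only
(`V`, `VA`, `VAO`). Similarly, the skeleton description places the nose in
the head, but the analysis grouping lists head as joints {15, 16, 17, 18};
the analysis grouping is taken as authoritative, and `body_part_joints("all",
include_nose = TRUE)` restores joint 0 if wanted.

## The synthetic cohort

No clinical recordings are distributable, so the generator is a first-class
module: every downstream stage is exercised on cohorts whose ground truth
is known in closed form. Each joint follows an anchored Gaussian random
walk in 3D; the per-axis step SD is
$\sigma = \texttt{base\_step\_sd} \times \lambda(\mathrm{group},
\mathrm{joint}, \mathrm{segment}) \times m_s$, where $m_s$ is a per-subject
lognormal multiplier (sdlog 0.15) giving between-subject variability.
Because the step is isotropic 3D Gaussian, the expected inter-frame
displacement is the chi-3 mean
$\sigma\sqrt{2}\,\Gamma(2)/\Gamma(3/2) = 1.5958\,\sigma$ — the quantity the
feature extractor estimates, available analytically for tests.

Defaults are the study conditions the analysis targets: 22 ASD and 25 TD
subjects, 30 Hz, the 840 s six-segment schedule, 3 mm base step SD, mean
confidence 0.9 with 2% dropout (dropout draws fall below the 0.5 filter by
construction, so the filter is exercised deterministically in expectation).
A `duration_factor` rescales the schedule; the test suite and the
acceptance script use 0.1 (an 84 s session, ~2500 frames), which keeps a
full cohort build under two seconds while leaving segment-level feature
standard errors far below the simulated group effects.

The `"reported"` effect preset emulates the *direction and localization*
of the reported group contrasts — strongly elevated ASD head movement in
all three stimulus conditions (λ = 3), milder leg and trunk elevation in V
(λ = 1.5) — not calibrated effect sizes, which the source analysis does not
report. A random walk is deliberately not a biomechanical model: there is
no oscillatory stereotypy waveform, no posture constraint, no sensor noise
model beyond confidence dropout. Passing tests therefore demonstrate that
the pipeline recovers known movement-magnitude structure, not that it would
attain any particular accuracy on real children.

Depth is kept positive by reflecting the walk at $z = 0.05$ m; with the
default anchors near 2 m the reflection is essentially never active, so
the chi-3 closed form is unaffected in practice.

## Group statistics

For each joint × segment cell the two groups are screened with Shapiro–Wilk
(per group, non-normal if either rejects at 0.05) and compared with the
two-sample Wilcoxon rank-sum test, two-sided. The source describes a
signed-rank test, which is a paired procedure; the ASD and TD children are
independent samples, so the rank-sum test is the statistically valid
default here, with `paired = TRUE` available as an escape hatch. The exact
null distribution is used when both groups have ≤ 20 observations and the
pooled values are tie-free, otherwise the tie-corrected normal
approximation with continuity correction. Significance tiers are `*`
p < 0.05, `**` p < 0.01, `***` p < 0.001. No multiple-testing correction
is applied by default across the ~150 cells, mirroring the original
analysis; `adjust = "BH"` adds Benjamini–Hochberg adjusted p-values.

## The classification stack

For one model (a joint set × stimulus set), the pipeline is:

1. **PCA** on the raw feature matrix, keeping the smallest number of
   components whose cumulative explained variance reaches 95%. PCA is
   *global* (fit on all subjects) by default, because the source describes
   dimensionality reduction before the cross-validation loop. This leaks
   unlabeled feature structure across folds; `pca_scope = "per_fold"`
   provides the leakage-free variant. Component signs follow a fixed
   convention (largest-magnitude loading positive) so runs are
   reproducible.
2. **LOSO loop.** Each subject is held out once. The training scores are
   normalized per column by the median and the *raw* median absolute
   deviation (no 1.4826 consistency factor — the factor is a monotone
   rescale absorbed by the kernel width, and the plain MAD is what the
   procedure states); the held-out subject is normalized with the training
   statistics. Columns with MAD 0 are centered only and flagged.
3. **SVM-RFE with correlation-bias reduction** ranks the components within
   each training fold. The elimination criterion is the change in the
   Gaussian-kernel dual objective when a feature is removed at fixed dual
   coefficients, $DJ(i) = \tfrac12 \alpha^\top H \alpha - \tfrac12
   \alpha^\top H_{(-i)} \alpha$; the feature whose removal changes the
   objective *least in magnitude* is eliminated. Magnitude, not signed
   value, is the operative reading: a removal that leaves the objective
   unchanged is exactly the removable one, while the signed criterion would
   paradoxically shield it behind noise features whose $DJ$ happens to be
   negative. Features correlated at $|r| \ge 0.9$ form groups whose
   members are scored by removing the whole group, so importance shared
   across near-duplicates is not diluted — with a Gaussian kernel a
   duplicated feature contributes twice to the squared distance, and
   removing one copy halves its kernel weight, degrading its apparent
   importance when the group is large. The ranking SVM uses cost 10 (the
   grid midpoint) and gamma $1/d$; these only order features, the
   classification hyperparameters are searched separately.
4. **Median-rank aggregation and kappa-optimized selection.** Per-fold
   ranks are aggregated by their median; every top-$k$ subset of the
   aggregated order (up to `top_k_max`) is evaluated over the 7 × 7
   cost × gamma grid (log-spaced on [0.1, 1000]) by full LOSO confusion
   metrics, and the configuration with the best Cohen's kappa is reported.
   Ties break toward fewer features, then higher accuracy, then smaller
   cost, then smaller gamma, making the selected model unique and runs
   byte-reproducible.

`top_k_max` defaults to 10: the published per-model selections use at most
3 features, and the search cost grows linearly in the number of candidate
subset sizes, so capping at 10 loses nothing the procedure would plausibly
select while keeping the 24-model grid tractable.

Cohen's kappa is computed from the pooled LOSO confusion counts as
$(p_o - p_e)/(1 - p_e)$ with $p_e$ from the marginal products;
`reconstruct_confusion()` inverts published per-model TPR/TNR rows back to
integer counts, which reproduces the published accuracy and kappa exactly
and is used as a worked-example check in the tests.

### Selection optimism on null data

Reporting the LOSO kappa of the configuration that *maximizes* LOSO kappa
is an optimistically biased estimate: on cohorts with no group difference,
the maximum over the few hundred candidate configurations is positive on
average (empirically ≈ 0.2–0.3 with 47 subjects, versus ≈ 0 for any fixed
configuration — the acceptance suite computes this). This is a property of
the published procedure itself ("optimized to achieve best Cohen's kappa"),
faithfully reproduced here, not an implementation artifact; an unbiased
protocol would nest the hyperparameter and subset search inside each
training fold. Users should read the reported kappa accordingly, and can
quantify the optimism for their own data with label permutations.

## Numerical and degenerate-input choices

- Timestamps must be strictly increasing; files are sorted on read and
  duplicate timestamps rejected.
- Pose files round-trip exactly: both the CSV and JSON-lines writers emit
  17 significant digits.
- An all-constant feature matrix is a hard error at PCA; a single constant
  column is harmless (MAD-zero pass-through).
- Fewer than 3 values per group skips the normality screen with a flag;
  fewer than 2 per group is an error for the rank-sum comparison.
- RFE requires both classes in the training fold; LOSO requires at least
  two subjects per class.
- All randomness flows from explicit seeds: per-subject simulation seeds
  and per-model seeds are derived deterministically from the master seed,
  so any model of a study can be reproduced in isolation.

## Problem sizes used by the tests

The test and acceptance suites run the full 47-subject study conditions at
`duration_factor = 0.1` (≈ 2500 frames per subject), 20-seed null-cohort
batches at the same size, and the complete 24-model grid once; smaller
6–16-subject cohorts back the unit tests. These sizes put the closed-form
displacement checks well inside 2% tolerance while keeping the whole suite
in the minutes range.

## Limitations

- The generator's random walk validates magnitude-based features only; it
  cannot support frequency-domain or bout-structure descriptors, which the
  analysis does not use.
- Global PCA and cross-fold median-rank aggregation leak (unlabeled)
  information across folds by design fidelity; `pca_scope = "per_fold"`
  removes the former but not the latter.
- The reported kappa is selection-optimistic (see above).
- Published headline accuracies stem from unreleased clinical recordings;
  nothing here can or does reproduce them from data. What is reproduced
  exactly is the internal arithmetic of the published per-model metrics,
  and, on synthetic cohorts, the recovery of planted effects.
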