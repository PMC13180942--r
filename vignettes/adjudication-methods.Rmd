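---
title: "ROI adjudication on a synthetic radiograph benchmark: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI adjudication on a synthetic radiograph benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracverify)
```

## The problem and the model

High-recall fracture detectors are tuned so that no fracture is missed:
a low confidence cut (0.25) and NMS at IoU 0.5 leave many spurious
proposals, concentrated on structures that genuinely resemble fracture
lines — the cartilaginous growth plate of pediatric bones, superimposed
cortical edges at joint crossings, and implants. This package implements
the downstream *adjudication* stage: a binary verifier applied per
region of interest (ROI) that never modifies the detector.

Each proposal is a box `b` with detector confidence `s`. The adjudicator
is a compact convolutional network over the cropped patch: a stack of
3×3, stride-2 convolutions with ReLU, global average pooling into a
d-dimensional feature `f`, L2 normalization `ψ = f / ||f||₂`, and a
two-layer perceptron over `[ψ; s]` ending in a sigmoid. Conditioning on
`s` lets the head learn when to trust or overrule the detector; the unit
normalization bounds the embedding scale so that subtle texture
differences, not intensity magnitudes, drive the decision.

Decisions are taken on the convex fusion `S = α·ŷ + (1−α)·s`. α and the
operating threshold τ are chosen on a patient-disjoint validation split
by maximizing F1; the test split is touched exactly once.

## Training, mining, calibration

Training minimizes focal loss with γ = 2 (cross-entropy damped by
`(1−p)^γ` on easy examples), Adam, early stopping on validation F1, and
best-epoch restoration. The reference recipe (50 epochs, learning rate
1e-4, batch 32) is available behind the `fidelity` profile; the default
desk profile uses 18 epochs at 1.5e-3 so that a full benchmark run takes
tens of seconds on one CPU. During training, validation F1 is computed
from `ŷ` at the fixed threshold 0.5; the fused operating point is
selected only after training, which avoids circularity between model
selection and threshold selection.

Hard-negative mining runs after every epoch (cadence K = 1). The initial
pool holds all positives P and a seeded half of the training negatives
N₀; the remaining negatives form a reservoir that the model can only
reach by scoring them above the mining threshold — mined records join
N_h with provenance `mined_neg`, and `|D'| = |P| + |N₀| + |N_h|` is
asserted after every merge. This mirrors the intended deployment loop,
where convincing false alarms are fed back into training, and it is what
gives mining-enabled models their measurable advantage: they see hard
confounders the baseline pool lacks. τ_mine is re-selected on the
validation split each epoch as the smallest candidate whose mined set is
contaminated by true positives at a rate of at most
`1 − precision_floor` (default floor 0.8); strict inequality
`S > τ_mine` is used throughout. Mined negatives persist across epochs
(the pool only grows); whether re-mining fresh each epoch would behave
differently is an open design point we resolved in favor of persistence,
matching the idea of a progressively expanded dataset.

Because mining needs a fused score before α has been selected, epoch-time
fusion uses the default α = 0.6; the final operating α is selected after
training. This ordering must be fixed somewhere, and fixing it at the
default keeps mining independent of the operating-point search.

Calibration is reported as ECE over 10 equal-width bins (last bin
right-closed, empty bins carry zero weight) and the Brier score.
Uncertainty is quantified by seeded percentile bootstrap (resamples with
a single label class are redrawn and counted); paired comparisons use
the Wilcoxon signed-rank test, exact for up to 25 untied non-zero
differences and normally approximated with tie correction otherwise. The
pairing unit is the per-resample metric difference on identical
bootstrap resamples.

## The synthetic benchmark

The generator emulates the ROI-level statistics of pediatric wrist
radiographs, not their photometry. A 256×256 scene holds 2 bright bone
bands (smooth shaft profile plus brighter cortical rims) on a noisy,
slowly varying background. Per bone:

- a **fracture** with probability 0.8: a thin (1.0–1.6 px), tilted,
  dark discontinuity crossing the band;
- a **growth-plate confounder** with probability 0.7: a wider
  (3.5–5.5 px), smooth, exactly transverse lucent band;
- an **overlap confounder** with probability 0.5: a second bright edge
  crossing the shaft;
- optional implant-like saturated blobs (off by default).

Boxes are analytic, with a 6 px minimum half-extent so that hairline
features carry annotation-realistic boxes. The mock detector proposes
one jittered box per fracture (coordinate noise 1 px), per-confounder
false positives with probability 0.75, and Poisson(0.6) random false
positives, each with a Beta-distributed confidence — true positives
skewed high (Beta(9, 1.5)), confounders intermediate-high (Beta(6, 2.5)),
random proposals low (Beta(2, 6)) — then applies the 0.25 confidence
floor and NMS at 0.5. These shapes encode the clinical premise that
detectors fire *confidently* on growth plates, which is precisely what
makes second-stage verification worthwhile, while keeping the raw
confidence informative enough that convex fusion is non-degenerate. An
`overconfident_detector_config()` variant shifts false-positive
confidences high to study calibration repair.

The default cohort (100 patients × 1 scene ≈ 370 ROIs at roughly 45%
positives, split 80/10/10 by patient) is a deliberate desk-scale
reduction of the clinical cohort the benchmark emulates (2,750 ROIs from
hundreds of patients); the bookkeeping arithmetic of that cohort is
checked exactly in the test suite. What the generator does *not* model:
anatomy-specific shapes, multi-view consistency, scanner physics,
annotation ambiguity. Passing tests on this benchmark therefore
demonstrate that the pipeline's machinery behaves as specified — not
that any particular clinical accuracy would be attained on real
radiographs.

ROIs are cropped with a 50% context margin on each side (the expert box
then covers ~25% of the patch, giving the pointing game a meaningful
chance rate), bilinearly resized to 64×64, and standardized inside the
model (mean 0.5, sd 0.25). Training-time augmentation applies ±10°
rotation, ±0.1 brightness, ±8% scale, ±0.06 shear and ±2 px translation;
evaluation is always augmentation-free. Labels follow the IoU ≥ 0.5 rule
against ground-truth fracture boxes, matching the IoU used for NMS and
evaluation.

## Numerical and design choices

- **Boxes** are 0-based, half-open pixel rectangles everywhere
  internally; YOLO-txt (center-normalized) and COCO-style (x, y, w, h)
  are converted only at the I/O boundary, with bit-exact round-trips.
- **Threshold candidates** for F1 maximization are midpoints between
  consecutive distinct scores plus {0, 1}; ties break toward the
  smallest τ (favoring recall). The α grid is 0.05-spaced; α ties prefer
  0.6, then smaller α.
- **NMS** is greedy by descending confidence with strict-inequality
  suppression and input-order tie-breaks.
- **mAP@0.5** uses single-class, all-points interpolation; duplicate
  detections of a matched ground-truth box count as false positives.
- **Grad-CAM** targets the last convolutional stage by default; channel
  weights are spatial gradient means; the map is ReLU-ed, bilinearly
  upsampled, max-normalized; masks use a relative threshold of 0.5 of
  the maximum; argmax ties break row-major so pointing results are
  deterministic.
- **Degenerate cases** are defined, not left to chance: 0/0 metric
  ratios are 0 with a flag, probabilities are clamped to
  [1e-7, 1 − 1e-7] inside the focal loss, zero-norm embeddings raise an
  error, an identically zero heatmap yields an all-zero mask.
- **Determinism**: every stage seeds its own RNG stream derived from one
  run seed; identical configuration and seed give bit-identical scenes,
  splits, training trajectories and reports.

The head's hidden width (64), the backbone widths (8, 16, 32, 64) and
the mining precision floor (0.8) are declared defaults — the framework
is agnostic to all three, and the fidelity profile swaps in a deeper
backbone at 224×224 without touching any other stage.

## The ablation ladder

The component ladder is reproduced on the synthetic benchmark as four
cumulative configurations sharing one cohort and split: (1) raw detector
confidences; (2) a patch classifier of identical capacity but with the
confidence input ablated, trained with mining — isolating what
hard-negative-augmented visual verification alone contributes; (3) the
full confidence-conditioned adjudicator; (4) convex fusion with
validation-selected α and τ. Median F1 across seeds is expected to be
non-decreasing down this ladder; individual seeds can deviate, since the
validation split that selects operating points holds only a few dozen
ROIs at desk scale.

## Known limitations

- The desk-scale validation split (~40 ROIs) makes selected thresholds
  noisy; seed-to-seed variation of single-run F1 is a few points, which
  is why directional claims are made on medians across seeds.
- The mock detector is parametric; none of its confidences come from a
  trained model, so absolute calibration numbers on this benchmark do
  not transfer to any real detector.
- Grad-CAM resolution at the last stage is 4×4 before upsampling;
  localization scores are correspondingly coarse (pointing is the most
  reliable of the three scores at this scale).
- Training is single-threaded and CPU-bound by design; the fidelity
  profile is provided for completeness but takes correspondingly longer.
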