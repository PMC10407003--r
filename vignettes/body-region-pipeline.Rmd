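---
title: "Body-region classification of tomographic slice stacks: models, rules and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Body-region classification of tomographic slice stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cross-sectional imaging exams (CT, MRI) are organized as
patient → study → series → image, and downstream systems — hanging
protocols, relevant-prior retrieval, automated AI triage — need to know
*which body regions* each series covers. The DICOM metadata that is supposed
to carry this (`BodyPartExamined`, procedure descriptions) is free-text,
site-dependent and frequently wrong, so `bodyregions` implements a
pixel-based alternative: classify every axial slice into one of 17 (CT) or
18 (MRI) body regions, then clean the per-slice labels with series-level
rules, and evaluate the result with statistics that respect the strong
spatial correlation between neighboring slices.

This package provides the full pipeline as tested, reusable components, and
a seedable geometric phantom generator so that every stage — filtering,
ground-truth propagation, preprocessing, training, rule-based
post-processing, bootstrap evaluation — can be exercised end to end at desk
scale without any clinical data.

## The class schema

The vocabulary covers the whole body: head, neck, chest, breast (MRI only),
abdomen, pelvis/hip, thigh, knee, calf, foot, shoulder, arm, elbow, forearm,
hand, and the cervical/thoracic/lumbar spine segments. Classes are ordered
alphabetically on their canonical snake_case names and the ordering is
frozen — the index of a class *is* the classifier output position, and
checkpoints store the vocabulary JSON to pin it.

Each region is delimited cranio-caudally by anatomical landmarks
(`landmark_table()`): the knee runs from the distal 6th of the femur to the
proximal 6th of the tibia, the abdomen from the diaphragm to the aortic
bifurcation, and so on. Two consequences shape the design:

* **Adjacent regions share landmarks** (the pelvis ends where the thigh
  begins), so instantiated intervals are half-open `[bottom, top)` and a
  slice exactly on a boundary belongs to the caudal region's top neighbor
  only once.
* **Spine segments overlap the body cavities** (a lumbar-spine slice is
  also an abdomen slice). The classifier is single-label per image, so
  overlaps are resolved by a declared precedence list
  (`default_precedence()`: spine segments, then breast, then the rest).
  This is a package convention — the underlying anatomy is genuinely
  multi-label, which is a known limitation of the single-label framing.

One *internal* class, `abdomen_chest`, models the thoraco-abdominal
junction, where slices genuinely show both cavities. It is never a final
output label: a series-level rule resolves it (below).

## Ground truth: thin 3D boxes in patient coordinates

Annotation uses thin axis-aligned 3D boxes in patient coordinates, one per
region. Because all series of an exam that share a frame of reference live
in the same patient coordinate system, a box drawn once labels the slices
of *every* registered series (`propagate()`): membership is slice-center z
inside the half-open `[z_min, z_max)`. Candidate sets are reduced to single
labels by `resolve_labels()` under the precedence list; empty sets mean
"unlabeled" and are excluded from training and evaluation.
`audit_labels()` implements the independent-review arithmetic used to check
annotation quality (discrepancy percentage over a seeded random sample).

## Preprocessing

Each slice is preprocessed independently (`preprocess_image()`):

1. compute the per-image mean and (population) standard deviation;
2. clip to `[mean − 4σ, mean + 4σ]`;
3. normalize as `(value − mean) / (2σ)`;
4. replicate the grayscale channel to three identical channels;
5. scale the longer side to 224 with bilinear interpolation and zero-pad
   the shorter side symmetrically.

Two numerical choices deserve a note. First, the clip/normalize pair maps
the clip bounds to ±2, so the chain's output range is `[−2, 2]` — the value
`±1` corresponds to ±2σ, and the padding value 0 codes mean intensity
(padding is applied *after* normalization for exactly this reason). Second,
a constant image has σ = 0; clipping is skipped and the normalized output
is defined as all-zero, since such a slice carries no signal and this avoids
a division by zero.

## The classifier backbone

The pipeline treats the slice classifier as pluggable: everything upstream
(preprocessing) and downstream (rules, evaluation) only depends on
per-slice probability vectors over the internal classes. The backbone
shipped here is deliberately compact: the 224×224 input is mean-pooled to a
16×16 grid (channels are identical, so one channel is pooled), flattened,
and passed through a single ReLU hidden layer (64 units by default) into a
softmax. It is trained with categorical cross-entropy using mini-batch Adam
(defaults: 10 epochs, batch 32, learning rate 1e-3), and the per-epoch mean
loss is recorded in the returned handle so training curves can be
inspected. Training, initialization, shuffling and augmentation are all
driven by one seed and are exactly reproducible.

Training-time augmentation follows the standard spatial policy for this
task: rotation within ±π/10, translation and shear up to 10% of image size
per axis, scaling within ±20% per axis, bilinear resampling (via EBImage's
affine transform), background filled with the mean-intensity code 0. The
reference description of the policy leaves open whether deformations hit a
fixed subset or random images each epoch; we re-draw a random subset each
epoch with per-image probability `apply_prob` (default 0.5), which is the
simpler contract to reason about and test.

Active learning is supported through `rank_uncertain()`: a study's
uncertainty is the mean over its slices of `1 − max probability` (a
normalized-entropy alternative is available), and the top-k (default 200)
most uncertain studies are returned for labeling. The margin-style score is
the simplest standard choice; nothing downstream depends on which score is
used.

## Series-level rules and smoothing

Per-slice argmax labels are noisy in predictable ways; the rule engine
(`postprocess_sequence()`) applies, in this fixed order:

1. **Transitional-class merge** — `abdomen_chest` slices are relabeled to
   chest or abdomen, whichever is predominant in the series; if neither
   occurs the fallback is abdomen, and a tie also resolves to abdomen (by
   analogy with the fallback).
2. **Breast-series rule (MRI)** — if at least 50% of slices are labeled
   breast, the whole series is breast (dedicated breast acquisitions are
   noisy and the spurious minority labels are wrong in practice).
3. **Outlier removal** — an interior run of length 1 flanked by agreeing
   labels takes the flanking label, repeated to a fixed point.
4. **Moving-average smoothing** — a moving average is undefined on
   categorical labels, so the window-3 filter averages the per-class
   *probability* sequences (edge windows truncated), renormalizes and
   re-takes the argmax. This is the only reading that uses the classifier's
   scores rather than inventing an ordinal coding of class labels.
5. **Confidence threshold** — slices with final confidence below 0.5 are
   marked indeterminate and excluded from confusion-matrix accumulation;
   the boundary is inclusive (0.5 is kept).

Because stages 1–3 edit labels while stage 4 operates on probabilities,
every label edit also moves the edited slice's argmax probability mass onto
its new class. Without this, smoothing would silently undo the rules (and
could even reintroduce the internal class). This bookkeeping is a package
design choice; it preserves each row's total probability mass.

## Evaluation: spatially aware bootstrap

Slices 2.5 mm apart are nearly identical, so naive per-image confidence
intervals are far too tight. `bootstrap_ci()` therefore resamples in a way
that respects the data's correlation structure:

* resample *studies* with replacement (patients are the independent unit);
* within each sampled study, pick one series at random (series of one study
  are strongly correlated);
* within each series, keep only slices at least 10 mm apart
  (`spatial_sample()`: greedy scan from a randomly offset start, so all
  pairwise kept distances are ≥ 10 mm based on slice position);
* accumulate the confusion matrix (rows = predictions, columns = truth) and
  record support-weighted F1, sensitivity and specificity.

The interval is the percentile interval over iterations (default 1000,
95%). Percentile rather than BCa because nothing in the method depends on
the refinement and percentile is the simplest defensible default. Weighted
sensitivity equals micro-averaged accuracy whenever every image is
evaluated — an algebraic identity the test suite asserts — which makes the
headline number easy to interpret.

Associations between correctness and confounding factors (manufacturer,
contrast, sequence family, ...) are reported as Pearson chi-squared (no
continuity correction) with Cramér's V = `sqrt(χ² / (n·(min(r,c)−1)))` on
the correct/incorrect × factor table, built from image-level flags.
`audit_dicom_tags()` implements the study-level tag audit: a study's
free-text tag is mapped through a configurable dictionary and counts as
accurate iff the mapped region is among the study's true regions.

## Study design helpers

`split_patients()` performs the 75/25 train/validation split stratified by
body region **on patient id**: per region, patients are shuffled under a
seed and split at `floor(0.75·n)`, and a patient appearing under several
regions is assigned once (first-listed region), so no patient can leak
across partitions. `required_images()` implements the survey sample-size
model `ceil(z²(1−p)/(r²p))` — 43 independent samples at p = 0.90, z = 1.96,
r = 0.10 — times an explicit `design_effect` (images per effective
independent sample). The design effect is exposed as a parameter rather
than hard-coded because its value depends on acquisition protocols (slice
spacing vs the 10 mm decorrelation scale) and is not derivable from first
principles.

## The phantom generator

`generate_study()` / `generate_cohort()` produce seedable studies with the
full hierarchy and metadata but deliberately simple pixels: each region is
a distinctive deterministic geometric texture (ring for head, paired
ellipses for chest, paired rings for pelvis, square outline for the
thoracic spine, ...), rendered per slice with additive Gaussian noise and
12-bit quantization. The generator's contract is *distinguishable,
geometry-consistent classes*, not realism. What it does emulate:

* the patient → study → series → image hierarchy, frame-of-reference
  geometry, and slice ordering — so DICOM round-trips, box propagation and
  spatial sampling are exercised for real;
* categorical acquisition metadata (manufacturer, contrast, sequence,
  institution, age band, sex) sampled from configurable distributions — so
  association statistics have factors to work on;
* transitional anatomy: at each boundary between adjacent regions the two
  textures blend linearly over a configurable transition zone, and inside
  the chest/abdomen zone training slices carry the internal
  `abdomen_chest` label — so the merge rule and the
  boundary-misclassification phenomenon are exercised.

Default conditions (chosen once as a plausible desk-scale case mix, and
documented here rather than tuned): slice spacing 5 mm, region extent
40 mm (8 slices per region), 3 contiguous regions per study drawn as
windows over an anatomically ordered ring, transition zone 10 mm (2 blended
slices per junction — boundary ambiguity in practice spans about a
centimeter, the same scale as the spatial-sampling threshold), noise SD 250
against a foreground contrast of 2500 (10%), 64×64 pixels. Region windows
are assigned round-robin over the ring so every class appears with
near-equal frequency.

What the phantoms do **not** model: anatomy, pathology, implants, scanner
physics, intensity distributions of real tissue, oblique acquisitions with
in-plane anatomy shift, or inter-patient variability beyond noise. A
passing end-to-end run therefore demonstrates that the pipeline's plumbing,
rules and statistics behave correctly on separable classes with the stated
geometry — it says nothing about clinical accuracy, which requires clinical
data and the full-scale transfer-learning backbone.

## Problem sizes used by the tests and the acceptance experiment

The headline desk-scale experiment (also run by `scripts/acceptance.R`)
uses an MRI cohort of 200 patients (one study each): a 75/25 patient split
leaves 150 training studies = 150 × 3 regions × 8 slices = 3600 training
slices (200 per class), with ~50 held-out test studies (~1300 evaluated
images), compact backbone, 10 epochs with the full augmentation policy.
The test suite runs smaller configurations of the same experiment for its
reproducibility and smoke checks, a 200-repeat coverage simulation for the
bootstrap (30 studies × 12 slices, accuracy 0.9, 150 iterations), and
1000-matrix brute-force cross-checks for the metric computations.

## Known limitations

* Single-label per slice: overlapping anatomy (spine vs cavities, shoulders
  in chest fields of view) is resolved by precedence, not represented.
* The compact backbone is intended for separable phantom classes; clinical
  deployment would swap in a pretrained deep backbone behind the same
  interfaces (checkpoint + vocabulary JSON + preprocessing tag).
* The DICOM layer is minimal by design: uncompressed Explicit VR Little
  Endian, single-frame, the tag subset the pipeline needs. Unsupported
  transfer syntaxes are logged as codec exclusions rather than parsed.
* The normalization formulas produce values in `[−2, 2]`; descriptions of
  this preprocessing sometimes state `[−1, 1]`, which the printed formulas
  do not yield. We implement the formulas and document the actual range.
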