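---
title: "Artifact detection and severity grading for fetal MRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact detection and severity grading for fetal MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riseqc)
```

## The problem

Fetal MR acquisitions are routinely degraded by three artifact families:
**motion** (blurring and ghost replicas from fetal movement during k-space
acquisition), **chemical shift** (fat/water spatial misregistration along
the frequency-encode axis, visible as thin dark/bright bands at tissue
boundaries), and **radio-frequency interference** (zipper lines and streaks
from stray RF sources). Detecting and grading them is normally the MRI
operator's job — subjective, slow and error-prone. `riseqc` implements an
automated quality-assurance pipeline: one convolutional network decides
*which* artifacts are present in a 2D slice (multi-label classification over
motion / chemical shift / radio-frequency / normal), a second, structurally
identical network regresses *how severe* each artifact is on a 0–3 scale,
and the two outputs are multiplied into a per-artifact score that a fixed
threshold table converts into the ordinal grades None / Mild / Medium /
Severe.

Because clinical fetal images generally cannot be shared, the package ships
a synthetic phantom and artifact simulator as a first-class, tested module:
every stage of the pipeline can be exercised end-to-end with data whose
labels are known by construction.

## Preprocessing

The networks consume masked, normalized, fixed-size slices. The pipeline
order is fixed:

1. **Mask overlay** (`overlay_mask`): everything outside the fetal
   segmentation is zeroed, so artifacts are only scored where they affect
   fetal tissue.
2. **Max-intensity normalization** (`normalize_slice`): each pixel is
   divided by the image maximum, mapping to $[0,1]$ while preserving pixel
   ratios. This is idempotent, and an all-zero slice (an empty mask) is
   rejected rather than silently propagated — the operation is undefined
   there and such a slice carries no tissue to grade.
3. **Resize** (`resize_slice`): bilinear interpolation to a square network
   input (canonically $512\times512$; smaller sizes are used throughout the
   tests). Masks are resized with nearest-neighbour interpolation so they
   stay binary.

Labels are encoded as a 4-long one-hot presence vector (motion, chemical
shift, radio-frequency, normal) plus a 3-long severity vector with values
in $\{0,1,2,3\}$ = none/mild/medium/severe. The invariants are enforced at
construction: an artifact flag is 1 exactly when its severity is positive,
and normal is 1 exactly when all severities are 0.

`split_dataset` shuffles deterministically under a seed and allocates
80:10:10. The rounding rule — floor for validation and test, remainder to
training — is one of several rules consistent with the canonical case
(2,250 slices → 1,800/225/225, which it reproduces exactly); it was chosen
because it is deterministic and never starves the training partition.
Splitting is at the slice level. `upsample_minority` balances the training
partition (only) by duplicating items of under-represented 4-flag patterns,
sampled with replacement under a seed, until every pattern reaches the
majority count; the class identity used for balancing is the full flag
pattern rather than only the normal class, since either reading is
defensible and the pattern-level rule also covers multi-artifact
imbalance.

## Architecture

Both networks share one body: a stem, six **RISE blocks**, global average
pooling and a dense head. A RISE block composes three mechanisms:

**Inception transform.** Four parallel paths — $1\times1$;
$1\times1\to3\times3$; $1\times1\to5\times5$; $3\times3$ max-pool
$\to1\times1$ — each produce `out_channels`/4 maps (so block widths must
divide by 4), concatenated along channels in path order. The $1\times1$
bottlenecks keep the parameter count down and the mixed kernel sizes match
the mixed spatial scales of the artifacts (motion is global, RF streaks are
local). Every convolution is stride-1 with same padding and a rectifier.

**Squeeze-and-excitation recalibration.** With feature maps
$I_n(i,j)$, $n = 1..C$:

$$S_n = \frac{1}{H W}\sum_{i=1}^{H}\sum_{j=1}^{W} I_n(i,j)$$

The squeeze vector $S$ passes through a bottleneck $C \to C/g \to C$ (two
affine maps with biases, rectifier $\delta$ between, sigmoid $\sigma$
after), giving per-channel attention weights $E_n \in (0,1)$, and the scale
layer multiplies each channel: $O_n = E_n \times I_n$. The reduction ratio
$g = 8$ is the published best value and the default; block widths must
divide by $g$ when SE is enabled.

**Residual addition.** The block input is added to the SE-recalibrated
branch. When input and output channel counts differ the input passes
through a $1\times1$ projection convolution; otherwise the identity is
used.

Each mechanism has an ablation toggle (`use_inception` replaces the
transform with a single $3\times3$ convolution, `use_se` skips the
recalibration, `use_skip` omits the addition), so the ablation variants are
ordinary configurations rather than separate code paths. The package
asserts only the *structural* correctness of each variant; performance
ordering between variants is a data question the synthetic corpus cannot
answer.

The heads differ only in the last layer: 512 dense units feed either 4
sigmoid outputs — independent probabilities, deliberately *not* a softmax,
because a slice can carry several artifacts at once — or 3 linear outputs,
one raw severity per artifact, unconstrained during training and clamped to
$[0,3]$ only at report time.

### Choices the architecture description leaves open

The following were fixed once as package defaults, all overridable in
`rise_config()`:

- **Stem**: 2 stages of $3\times3$ convolution (32 channels) → dropout
  (rate 0.25) → $2\times2$ max-pool. A modest footprint ahead of the six
  RISE blocks.
- **Inter-block downsampling**: $2\times2$ max-pool after every second
  RISE block, keeping $512^2$ inputs tractable.
- **Block widths**: a doubling ladder from the stem width capped at 256
  (32, 64, 128, 256, 256, 256).
- **Dense-head input**: global average pooling, so the dense parameter
  count is independent of the input size.
- **SE placement**: after the inception concatenation, before the residual
  addition.
- **Head independence**: classifier and regressor share no weights; they
  are two parallel networks.

## Training

`rise_net()` trains with Adam (defaults $\beta_1=0.9$, $\beta_2=0.999$,
$\epsilon=10^{-8}$) at the published learning rate $10^{-5}$, 100 epochs,
batch size 8. The classifier minimises binary cross-entropy averaged over
the four independent output nodes, with probabilities clamped at
$\varepsilon = 10^{-7}$; the regressor minimises mean squared error over
the three severities. Early stopping is available but off by default, and
the final-epoch weights are the ones evaluated (selectable). The epoch
shuffle, weight initialisation and dropout masks all derive from one seed,
so training is bit-reproducible on one platform.

`cross_validate()` runs k-fold (default 5) cross-validation: seeded
disjoint folds, each item validated exactly once, per-fold metrics
summarised as mean ± standard deviation. The fixed 80:10:10 test split and
cross-validation coexist by holding the test split out first and
cross-validating the remainder — the only reading consistent with
reporting a separate test set.

The metric for the classifier is **exact-match accuracy**
$\frac{1}{n}\sum_i 1[Y^{true}_i = Y^{pred}_i]$ over the whole thresholded
4-flag vector (decision threshold 0.5, strict inequality, configurable),
the strictest of the monitored metrics: it can never exceed any per-class
binary accuracy. Per-class confusion counts give precision $TP/(TP+FP)$,
recall $TP/(TP+FN)$ and their harmonic mean F1; zero denominators yield an
explicit `NA` rather than 0, so small folds cannot silently inflate
summaries. For the regressor, the per-artifact MSEs are aggregated into an
overall value as their unweighted mean — the aggregation is pinned down by
the published per-class values (0.097, 0.079, 0.073) averaging to the
published overall 0.083.

## Scoring and grading

For each artifact, `total_severity()` multiplies the detection probability
by the clamped severity; `grade()` applies the threshold table

| score | grade |
|---|---|
| $\le 0.5$ | None |
| $(0.5, 1]$ | Mild |
| $(1, 2)$ | Medium |
| $\ge 2$ | Severe |

As printed, the source table's Medium and Severe rows overlap at exactly 2;
this implementation resolves score 2.0 to **Severe** — the stricter
clinical reading, since under-calling a severe artifact is the costlier
error — and covers the boundary with a test. The normal probability never
enters a product (there is no fourth severity); a slice is reported Normal
exactly when all three grades are None. `make_report()` renders the
per-artifact table and a one-line summary (`"Motion: Medium, CS: Severe,
RF: Severe"`) that `parse_severity_report()` inverts.

## The synthetic phantom and artifact simulator

`make_phantom()` draws `n_blobs` smooth ellipses (random centres, axes,
orientations, peak intensities in `intensity_range`) with a
$(1-q)^{0.25}$ radial falloff and a mild low-frequency texture, on a black
background; the mask is exactly the blob union, and the image is zero
outside it — i.e. the phantom is born in the masked-overlay representation
the networks consume. Everything is a pure function of the spec and seed.

The three corruption operators are *stand-ins with the right phenomenology*,
not reconstructions of any radiologist's grading rules (no such rules are
published), and severity maps to operator parameters linearly — monotone
and testable, with no claim of clinical calibration:

- **Motion** (`inject_motion`): random per-line phase errors on a fraction
  $0.1k$ of phase-encode lines of the 2D DFT at severity $k$, sparing the
  lowest sixteenth of spatial frequencies so gross anatomy survives. The
  corrupted line set is *nested* across severities at a fixed seed —
  severity 3 corrupts a superset of severity 1's lines with identical
  phases — so image deviation is monotone in severity by construction
  rather than by accident of sampling.
- **Chemical shift** (`inject_chemical_shift`): a dark band of width $k$
  pixels inside one horizontal tissue boundary (intensity × 0.15) and a
  matched bright band (+0.35, clipped) on the opposite boundary, the
  horizontal axis standing in for the frequency-encode direction. Pixels
  farther than $k$ from the boundary are untouched.
- **RF** (`inject_rf`): by default $k$ k-space spikes at mid/high spatial
  frequencies (coherent stripe patterns); a `zipper` mode draws $k$ short
  alternating bright-pixel segments instead. Spike/segment positions are
  drawn once per seed and used in nested order.

Severity 0 is the exact identity for every operator, all operators preserve
shape and the $[0,1]$ range, and `generate_dataset()` samples recipes from
a 4-class mix (default 0.30/0.25/0.25/0.20 with normal smallest, mirroring
the clinical situation where artifact-free scans are the minority), adding
a second artifact with probability 0.25 so the multi-label aspect of the
task is actually exercised. Corruption order is chemical shift (an
image-domain boundary effect), then motion (which realistically blurs the
band), then RF.

**What passing tests do and do not show.** The simulator emulates masked
fetal-like anatomy with graded, labelled corruptions; it does not simulate
MR signal equations (SSFP/HASTE), field-strength effects, bias fields, 3D
volumes, or the visual criteria the consensus radiologists actually used.
Tests against it demonstrate that the pipeline is implemented correctly and
can learn its labels — not that the published clinical accuracies transfer,
which would require the private clinical corpus and GPU-scale training.

## Numerical and engineering choices

- Convolution and pooling kernels are compiled (im2col + matrix product,
  with the exact adjoint for the backward pass); everything else is plain R
  matrix algebra. Gradients of every layer are verified against numerical
  differentiation in the test suite.
- He-scaled Gaussian initialisation throughout; the excitation bottleneck
  carries biases.
- Dropout is inverted (train-time scaling) and disabled at inference, so
  prediction is deterministic.
- Binarisation ties (probability exactly at threshold) resolve to 0.
- A non-finite training loss raises a divergence error naming the epoch.
- One user-facing seed fans out into per-module sub-seeds via a seeded
  draw, and all stochastic code funnels through a save/restore RNG helper,
  so `(spec, recipe, seed)` determines every output bit without disturbing
  the caller's RNG state.

### Problem sizes used in the shipped checks

The deterministic checks run at full published sizes (the 2,250-slice split
arithmetic is computed on 2,250 actually-generated slices). The learning
demonstration runs at desk scale as the package's own choice of
demonstration size: 300 synthetic $64\times64$ slices, a width-reduced
configuration (stem 8 channels, block widths 8–32, 64 dense units), 10
epochs at learning rate $10^{-3}$, batch 8. At $10^{-5}$ — the default, and
the published value for the full-size problem — a 10-epoch run at this
scale barely moves the weights; the demonstration uses the larger rate and
reports exact-match accuracy against the empirical majority-pattern
baseline of its validation split. The all-ablations-off variant (plain
$3\times3$ convolution blocks) is trained briefly to confirm it remains
numerically stable.

## Known limitations

- The simulator's operators are phenomenological; absolute severity scales
  are arbitrary (severity 2 motion is not calibrated to any clinical
  grade).
- Training is single-threaded CPU R; it is meant for desk-scale
  experiments and correctness work, not for training on $512^2$ clinical
  volumes at the published 100-epoch budget.
- Slice-level splitting can leak anatomy between partitions when several
  slices come from one subject; subject-level splitting must be done by
  the caller if subject identifiers exist.
- No artifact *correction* is attempted, and no DICOM/NIfTI ingestion —
  the pipeline consumes exported PNGs.
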