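---
title: "MaxGRNet: model, faithfulness protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MaxGRNet: model, faithfulness protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science implemented by `maxgrnet`: the
network, the explanation-faithfulness protocol, the statistical
machinery, the synthetic phantom generator that stands in for real
fundus data at desk scale, and the numerical and design choices that
were genuinely open.

## The model

`maxgrnet()` builds a hierarchical multi-axis vision transformer. An
input image (`input_size` pixels square, three channels, normalized
with the standard mean/std constants) passes through:

1. **Stem** — two 3×3 convolutions, the first with stride 2.
2. **Stages S1–S4** — each stage begins by halving the spatial
   resolution and then repeats, `stage_depths[s]` times, the block
   triple **MBConv → block attention → grid attention**:
   * *MBConv*: pre-norm, 1×1 expansion (`mlp_expansion`), GELU, 3×3
     depthwise convolution (stride 2 at stage entry), squeeze-excitation
     gating (`se_ratio`), 1×1 projection, residual. The downsampling
     shortcut is 2×2 average pooling plus a 1×1 projection.
   * *Block attention*: multi-head self-attention with a learned
     relative-position bias inside non-overlapping `P × P` windows
     (`P = partition_size`) — local context at linear cost.
   * *Grid attention*: the same computation over a dilated grid that
     samples every `(H/P)`-th position, so each group spans the whole
     image — global context at the same cost.
   Both attention halves are pre-normalized and residual:
   `x + Attn(LN(x))` followed by `x + MLP(LN(x))`.
3. **Head** — global average pooling, layer normalization, and a linear
   classifier over `num_classes`.  `model_embeddings()` exports the
   pooled, normalized penultimate features for embedding-space analyses
   (external projection or clustering tools).

### The GRN-MLP

The defining modification is the feed-forward block. With
`grn_enabled = TRUE` the transformer MLP becomes

```
fc1 (C -> C*mlp_expansion) -> GELU -> GRN -> fc2 (-> C)
```

where Global Response Normalization acts per sample on the expanded
feature map: each channel is aggregated to its spatial L2 norm
`g_c`, normalized across channels, `n_c = g_c / (mean_c g + eps)`, and
the input recalibrated as `gamma_c * (x * n_c) + beta_c + x`. GRN
promotes channel contrast: channels that respond strongly over the
image are amplified relative to weak ones, which counteracts feature
collapse in the expanded MLP representation.

Two readings of GRN exist: a parameter-free operator, and the
formulation with learnable per-channel `gamma`/`beta`. We implement the
learnable form initialized at zero — which *is* the parameter-free
operator at initialization because of the residual term — and provide
`grn_frozen = TRUE` to pin `gamma = beta = 0` permanently. The package
does not guess which was intended; the switch exposes both.

Two further choices were open:

* **Placement**: GRN sits between the activation and the projection,
  following the convention of the architecture that introduced it.
* **Spatial extent**: GRN could aggregate per attention window or over
  the full feature-map grid. The full grid is implemented (the MLP acts
  on the unpartitioned map): the operator is global by design, and a
  per-window variant would make the MLP's output depend on the
  partition type it follows.

With `grn_enabled = FALSE` the identical code path runs the plain MLP,
giving a controlled "GRN off" comparison: at initialization the two
configurations produce bit-identical outputs (verified in the tests),
so any later difference is attributable to training dynamics.

### Initialization

All weight matrices use a truncated normal (±2 sd) with
fan-in-scaled sd `sqrt(2/fan_in)`; GRN `gamma`/`beta`, relative-position
bias tables, norm offsets and biases start at zero. We initially used a
flat sd of 0.02 everywhere (a common transformer convention) and found
it catastrophic here: paths without a residual identity — the stem
convolutions and the pooled-projection shortcut at stage entries —
attenuate activations by roughly `0.02 * sqrt(fan_in)` per layer, and
after five such layers the logits were numerically independent of the
input. Fan-in scaling keeps the signal path magnitude-stable while the
residual branches still start near-identity (GRN at zero, biases at
zero).

### Training

`train_model()` minimizes softmax cross-entropy with Adam and decoupled
weight decay on weight matrices. The reference configuration is 50
epochs, batch 64, learning rate 1e-5, weight decay 3e-5; desk-scale
phantom runs use larger learning rates (2–3e-3) and few epochs. Two
stabilizers are on by default and matter at desk scale: global
gradient-norm clipping (`clip_norm = 1`) and a linear learning-rate
warmup over the first 10% of steps (`warmup_frac = 0.1`). Without them
a noticeable fraction of short runs collapsed to a single-class
predictor. Everything is seeded: the same seed, data and initial
weights reproduce the final weights bitwise on CPU.

## Grad-CAM

`gradcam()` computes the gradient of the **pre-softmax logit** of the
target class (the standard choice; probabilities would only rescale the
map) with respect to a convolutional feature layer, averages the
gradient spatially per channel, forms the rectified weighted channel
sum, and upsamples bilinearly (cell-centre convention) to input
resolution. The default layer is the depthwise convolution of the last
stage's final MBConv — the "last convolutional layer" of the hybrid
network — and `model_layers()` lists all alternatives.

At desk scale the layer choice matters: a 64-pixel tiny model reaches
stage S4 at 2×2 resolution, which carries almost no spatial
information, and *which* early layer localizes best varies with the
training trajectory. The desk-scale protocol therefore selects the
layer automatically: among the S1/S2 conv and depthwise layers, it
takes the one whose saliency concentrates best inside the generator's
ground-truth lesion masks on correctly classified validation images —
a rule only available because phantoms carry masks. Localization is
reported as *mass concentration*: the fraction of saliency mass inside
the lesion mask relative to the mask's area fraction (~15%); the
selected layer of the trained tiny model concentrates several-fold
above area chance, but a perfectly tight peak is not achievable by a
rectified, spatially averaged CAM at 8×8 or 16×16 resolution — a
resolution limit of the method, not a defect of the model.

## Insertion/deletion faithfulness

For one image and a saliency map, pixels are ranked by decreasing
saliency (ties broken by row-major index, so the procedure is
deterministic). The **deletion** curve replaces the top `t` fraction of
pixels (all three channels) with a Gaussian-blurred baseline of the
same image and records the softmax confidence of the target class; the
**insertion** curve starts from the blurred baseline and restores
original pixels in the same order. Both integrate to AUCs by the
trapezoid rule over `t ∈ [0, 1]`; a faithful explanation has high
insertion AUC and low deletion AUC (equivalently, high 1−deletion).

Protocol details, all configurable in `blur_config()` and
`evaluate_faithfulness()`:

* **Baseline**: per-channel Gaussian blur, kernel 51, σ = 8, clipped to
  the valid range; 50 steps by default. A black baseline exists for the
  closed-form toy oracles. Blur is the primary baseline: it removes
  information without leaving out-of-distribution black holes.
* **Step granularity**: the pixel count is divided as evenly as
  possible over the steps, remainder on the earliest steps; the stored
  fractions are the realized ones, so the endpoints are exactly the
  original image (`t = 0` deletion) and the fully blurred image.
* **Correct-only**: images the model misclassifies are excluded and the
  target class is the predicted class, so the curves measure the
  explanation of a decision the model actually made.
* Normalization commutes with both blurring (the kernel sums to one)
  and pixel substitution, so the curves run in raw `[0, 1]` image space
  with the normalization inside the scorer — exactly equivalent to
  perturbing normalized tensors.

Summaries report mean AUCs with seeded percentile-bootstrap 95%
confidence intervals; per-image results carry stable ids so two models
can be compared on the intersection of their correct-only sets
(`common_subset_pairing()`), with paired t and exact Wilcoxon
signed-rank tests.

## Statistics

* `bootstrap_mean_ci()`: percentile bootstrap, 10,000 replicates by
  default, seeded; an exhaustive mode enumerates all `n^n` resamples
  for tiny samples (used by the tests as an oracle anchor).
* `paired_t_test()`: two-sided, CI from the t distribution with
  `n − 1` degrees of freedom; zero-variance differences are a hard
  degenerate-input error rather than a p-value of `NaN`.
* `wilcoxon_signed_rank()`: zero differences dropped, mid-ranks for
  ties, exact null distribution by dynamic programming over doubled
  ranks for `n ≤ 25` (so mid-ranks stay exact), normal approximation
  with tie and continuity correction above. At `n = 5` with all
  differences of one sign the two-sided p is exactly `2/2^5 = 0.0625`
  — the smallest attainable value, which is why small-k fold
  comparisons bottom out there.
* `holm_adjust()`: Holm–Bonferroni step-down over one family of
  contrasts (e.g. the four baseline comparisons per metric; accuracy
  and F1 families are corrected separately).

## Evaluation harness

`confusion_and_metrics()` derives per-class one-vs-rest TP/FP/TN/FN and
accuracy/precision/recall/F1 from the confusion matrix, macro averages
them unweighted, and reports trace/total as the overall accuracy.
Ratios with zero denominators report 0 with a warning (the reference
datasets never hit this case; random tiny fixtures can).
`ovr_roc_auc()` computes per-class ROC curves against the pooled rest
and trapezoid AUCs (equal to the Mann–Whitney statistic with half
credit for ties). `stratified_kfold()` keeps per-fold class proportions
within one sample of the global proportions under a seeded shuffle;
stratification is the default (the reference data are balanced), and
`run_crossval()` accepts `stratify = FALSE`. Fold standard deviations
use denominator `k − 1`.

## Data pipeline

`dataset_index()` scans a class-per-subdirectory tree; image ids are
the relative paths. `split_holdout()` assigns stratified subsets by
largest-remainder apportionment. `plan_balancing()` implements
split-then-augment balancing: each subset independently receives
augmented copies (round-robin over a seeded shuffle of its real
parents) until it reaches its share of the per-class target — 2000 at
70:20:10 gives 1400/400/200. An index in which any augmented record's
subset differs from its parent's is a leakage violation;
`verify_no_leakage()` returns all violations and the orchestration
refuses to proceed on any. Balancing validation/test subsets with
augmented variants inflates evaluation sets with synthetic images; the
pipeline implements it as specified for the imbalanced-data protocol,
and simply omitting the `val`/`test` entries from the ratios gives the
train-only variant.

Augmentation is horizontal/vertical flips (p = 0.5 each), color jitter
(brightness, contrast, saturation factors in `1 ± 0.2`), and a light
3×3 Gaussian blur with σ uniform in `[0.1, 2]` — magnitudes chosen as
mild, label-preserving perturbations since none were prescribed.
Resizing is plain bilinear to 224×224 (aspect ratio not preserved).

## The phantom generator

`generate_phantoms()` emulates the structure of a four-class fundus
classification set: a bright reddish disc on a dark background with an
optic-disc highlight, plus one class-discriminative, spatially
localized feature per non-normal class, and a per-image binary lesion
mask that contains the feature entirely:

* *normal* — plain disc, empty mask;
* *cataract* — thin bluish-white streaks inside the lesion region;
* *retinopathy* — 18–24 small bright exudate-like dots;
* *glaucoma* — an enlarged pale cup rim (thin ring with radial spokes).

Design intent, in order of priority: (1) classes separable by a small
model in a few CPU minutes — a 3-nearest-neighbour classifier on raw
16×16 pixels exceeds 90% held-out accuracy, and the ~0.11M-parameter
tiny model reaches ≥95% validation accuracy within six epochs; (2)
features *thin* enough that the Gaussian-blur baseline genuinely
destroys the class evidence — filled color regions survive blurring,
which would make insertion/deletion curves flat and the faithfulness
protocol vacuous; (3) lesions confined to a known region so saliency
can be scored against ground truth. Nuisance variation (disc position,
base color, optic-disc position, lesion placement) is kept small for
the same reason. The generator is deterministic per seed.

What the phantoms do **not** emulate: vessel trees, texture, camera
vignetting, inter-class visual similarity, label noise, or class
imbalance. Passing tests on phantoms therefore demonstrate that the
pipeline is correct and that the protocol behaves as designed — not
that any accuracy or faithfulness level transfers to real fundus
images, which require full-scale training outside this package's
desk-scale scope.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own desk-scale study conditions: 240 phantoms
(60 per class, 64 px) with a 192/48 train/validation split for the
shared trained model (4 epochs, batch 8, learning rate 2e-3 — enough
for ≥95% validation accuracy while keeping the softmax calibrated;
longer runs saturate the probabilities and wash out the
insertion/deletion dynamics); 160
phantoms and 8 epochs per fold for the five-fold GRN-on/off
cross-validation; 120 images at 20 blur steps for the Grad-CAM vs
random faithfulness comparison in the tests, and 60 images at 15 steps
in the acceptance script's smoke. Exact worked-example quantities
(accuracy from printed counts, balancing counts, fold-mean deltas, the
1−deletion complement) are recomputed from their printed inputs and are
seed-independent.

## Known limitations

* Pure-R training: practical for the tiny phantom models; full-size
  224-pixel training is out of scope by design.
* Grad-CAM resolution at deep layers of small models limits mask-level
  localization (see above); the layer is configurable.
* The exact Wilcoxon p is computed for `n ≤ 25`; beyond that the
  normal approximation is used.
* Short desk-scale training remains stochastic: individual runs can
  undertrain, which is why the comparison harness pins seeds, shares
  fold splits and initial weights across arms, and reports per-fold
  vectors for paired tests rather than single-run differences.
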