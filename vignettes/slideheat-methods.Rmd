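---
title: "Methods: patch-based WSI classification with heatmap features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based WSI classification with heatmap features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models the package implements, the choices that
were genuinely open, and what the synthetic experiments do and do not
show. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The two-stage model

Whole-slide histology images are orders of magnitude too large for a
single network pass, so slide classification is factored into two
learners:

* a **patch classifier** *f*: 1,024 × 1,024 RGB patch → (p_normal,
  p_tumor), a convolutional backbone followed by global average pooling,
  a 1,024-unit fully connected layer and a 2-way softmax. Training uses
  Adam with learning rate 0.001, categorical cross-entropy, minibatches
  of eight, and keeps the parameters with the highest validation accuracy
  (earliest epoch on ties). Weights are randomly initialized — no
  transfer learning;
* a **slide classifier** *g*: 36 heatmap statistics → p_cancerous, a
  gradient-boosted decision-tree ensemble (100 trees, learning rate 0.1,
  exact greedy splits — on cohorts of tens of slides the histogram
  split-finding sketch can place a cut inside a class cluster instead of
  the between-class gap — single-threaded and seeded).

Between the two sits the malignant-probability heatmap: patch
probabilities arranged on the tiling grid, with background patches
(near-white, > 80% of pixels with all channels above 220) flagged and
excluded from the statistics. The 36 features are, in order: mean,
variance, standard deviation, median, mode, minimum, maximum, range and
sum of the normal probabilities (f1–f9) and of the tumor probabilities
(f10–f18); the count N_p of patches whose class probability falls in each
of the eight half-open bands (0.999, 1], (0.99, 0.999], (0.95, 0.99],
(0.9, 0.95], (0.8, 0.9], (0.7, 0.8], (0.6, 0.7], (0.5, 0.6], for each
class (f19–f34); and two numeric winner labels: the class with the larger
mean probability (f35) and the class winning the per-cell argmax count
(f36). The pipeline is deliberately not end-to-end: the heatmap is an
interpretable intermediate a pathologist can read.

Decisions that the source material left open, resolved here:

* **Band boundaries.** "P > 0.999" is taken literally: boundaries belong
  to the lower band, so `band_of(0.999)` is the (0.99, 0.999] band.
* **Mode of a continuous probability.** Ill-defined as stated; computed
  after rounding to two decimals, most frequent value, ties resolved to
  the smallest value.
* **Variance convention.** Population moments (divide by n), matching the
  array-programming default a Python implementation would inherit.
* **Winner-label ties** break toward tumor — the clinically conservative
  direction for a screening tool.
* **Class encoding** 0 = normal, 1 = tumor.
* **Both probability columns are raw softmax outputs**; nothing is
  recentered, so the per-class statistics obey mean_n = 1 − mean_t,
  var_n = var_t, sum_n = n − sum_t (asserted as a test invariant).

## Tiling and augmentation

Coordinates are 0-based, y-down, with half-open pixel windows
[x, x + size). Inference tiling uses stride = patch size
(non-overlapping), which matches the blocky heatmap rendering and gives
each grid cell exactly one prediction. Patch labels on annotated slides:
carcinoma if at least half the pixels fall inside a tumor polygon, normal
if none do, unlabeled otherwise.

For segmentation, each 1,024 patch is subsampled into 256 × 256 tiles at
half-overlap stride 128. A factor-of-64 dataset increase forces eight
offsets per axis, so the last offset overhangs the patch edge by 128 px;
the overhang is completed by mirror padding (edge pixel included) and
cropped again before stitched averaging. This is the only offset
convention consistent with 64 tiles per patch, and it makes
stitch-of-subsample the exact identity on constant images (a test
invariant).

Augmentation is the dihedral subset {rot90, rot180, rot270, fliph,
flipv}; labels are inherited from the parent patch, and split assignment
happens at the parent level before augmentation, so no augmented
descendant can leak across splits. Balanced manifests derive per-split
targets from parent counts (at least one parent per split, capacity six
variants per parent), approaching the 8:1:1 train/validation/test
proportions of the reference data distribution as counts grow.

## The network engine

No deep-learning framework is used: convolutions (stride 1, "same"
padding via im2col), 2 × 2 max pooling, global average pooling, dense
layers, instance normalization, softmax/sigmoid heads, explicit
backpropagation and Adam are implemented in base R and verified against
finite-difference gradients in the test suite. This caps throughput, so
the shipped presets are sized for tens of thousands of optimizer steps,
not millions:

* `small_cnn`: four 3 × 3 conv blocks (8→16→32→64 channels), 32-px
  input, ~93k parameters — the preset used by every experiment here.
* `inception_v3_class`: a deeper five-block preset (up to 256 channels,
  96-px input) with the same GAP → 1,024 → softmax head, for users who
  want the full-scale configuration shape; it is not a literal
  re-implementation of the published backbone.

Patches are resized to the network input by exact block mean-pooling
(bilinear interpolation when sides do not divide) and scaled to [−1, 1]
per channel, the cited backbone family's convention.

**U-Net.** Encoder/decoder with two 3 × 3 conv blocks per level,
nearest-neighbour upsampling, skip concatenation, "same" convolutions
throughout (so tile output size equals input size, which is the stated
motivation for half-overlap subsampling), and a sigmoid 1 × 1 output
head. The soft dice loss (1 − (2Σpt + ε)/(Σp + Σt + ε), ε = 1 in
training for stability, ε = 0 when reporting) has a treacherous loss
surface: its per-pixel gradient pushes positives up harder than it
pushes negatives down, so predictions drift toward the trivial
all-positive constant and saturate there. Four standard countermeasures
keep training reliable:

* **instance normalization** (learnable affine) inside the deeper conv
  blocks — but *not* in the first encoder level or the final decoder
  fusion, because per-sample normalization erases absolute intensity and
  this input → skip → output path is what carries the tissue's overall
  darkness;
* an **output-logit clamp** at ±4, so the sigmoid never saturates fully
  and an all-positive excursion stays recoverable;
* a 20-step **learning-rate warmup**;
* **collapse detection with restarts**: a fit whose validation
  predictions are essentially all positive is retrained from a shifted
  initialisation (up to three attempts, best validation dice kept) — the
  same pragmatic multi-start used for degenerate clustering fits.

With these, the desk-scale preset (`unet_test_config()`: depth 2, 16
base filters, 64-px inputs, batch size 2, learning rate 0.03) reaches
high validation dice within five epochs on the synthetic textures. The
classifier keeps plain conv-relu blocks: instance normalization would
subtract exactly the per-sample channel means that global average
pooling feeds the head. The U-Net learning rate and batch size are free
choices (the source protocol specifies them only for the classifier).

The training dice is computed **over each minibatch jointly**, not per
tile. Per-tile soft dice gives a tile whose truth mask is all zero a
gradient three orders of magnitude weaker than its neighbours', so a
per-tile loss never learns to suppress tumor-free tiles and the stitched
map over-covers — the same over-coverage the two-stage design is known
for. Batch-level dice restores a balanced gradient; reported validation
dice remains the per-tile average (matching how per-patch dice tables
are aggregated).

"Jitter" augmentation is defined as a per-channel brightness shift
uniform in ±5% of the dynamic range, alongside random horizontal flips —
small enough to leave the tissue palette informative, large enough to
discourage pure brightness thresholds.

**Grad-CAM.** Channel weights are the spatially averaged gradients of
the target class's pre-softmax score at a convolutional layer (default:
the last one); the rectified weighted activation sum is bilinearly
upsampled to the patch size and min-max normalized, with all-zero maps
left all-zero. A hand-built single-1×1-conv model reduces Grad-CAM to a
rectified channel combination, which the tests check analytically.

## The synthetic cohort

`generate_slide()` draws tumor regions as perturbed star-convex polygons
(14 vertices, radii jittered 0.75–1.05× around a region radius of
0.28–0.38 of the short slide side — large enough that a lesion fully
covers at least one 1,024 patch on the default 4,096² canvas, which
yields the smallest grid, 4 × 4, on which all 36 features are
non-degenerate). Inside the polygons: dense dark nuclei (2.5 blobs per
10⁴ px², radius 4–8 px, RGB (70, 40, 100) on (220, 185, 210)); outside:
sparse pale texture (0.4 blobs per 10⁴ px², radius 3–6 px,
RGB (170, 130, 190) on (235, 210, 225)); Gaussian intensity jitter with
SD 6 everywhere. The two classes differ in patch mean intensity by far
more than three pooled standard deviations (a test invariant), so a
small CNN can learn the task — by design. Every random choice flows from
one integer seed, and equal seeds give byte-identical slides.

What the generator does **not** emulate: real H&E stain variation,
nucleus morphology, scanner artifacts, tissue folds, or the ambiguous
boundary regions that make real PDAC hard. Passing the synthetic
acceptance run shows the pipeline's plumbing and learning dynamics are
correct, not that the model would reach comparable accuracy on clinical
slides.

## The end-to-end experiment

`run_synthetic_experiment(seed)` generates 24 slides (12 normal /
12 cancerous, alternating; 4,096² px; two tumor regions per cancerous
slide), splits them half/half into training and held-out testing, and
runs both stages plus segmentation:

* The patch classifier trains on a balanced augmented manifest drawn
  from half-stride (512 px) sampling of the training slides — training
  patches may be sampled freely, only inference is tied to the
  non-overlapping grid — for 5 epochs.
* By default the run is **cross-fitted**: the training slides are split
  again, the patch model fits on one half, and the booster's training
  heatmaps come from the other half, so the slide model never sees
  heatmaps of slides the patch model was fitted on (`crossfit = FALSE`
  reproduces the optimistic scheme that reuses the same slides for both
  stages). Either way, reported slide accuracy comes from the 12
  held-out slides.
* The U-Net trains on 120 quarter-resolution half-overlap tiles from
  tumor-boundary patches (plus 24 validation tiles) for 10 epochs and is
  evaluated by stitching all tile predictions of one held-out cancerous
  slide into a slide map, thresholding at 0.5, and computing unsmoothed
  dice against the rasterized polygon truth at the same quarter
  resolution. At quarter resolution the class signal is dominated by the
  tissue color contrast (the nuclei shrink to one or two pixels), so the
  experiment uses a one-level, 8-filter U-Net — small enough that the
  optimizer's step budget reaches a sharp solution reliably; the deeper
  presets remain available through `segmentation_config()`.

Problem sizes (24 slides, 5 epochs, 120 tiles, quarter-resolution
segmentation) were chosen once as the smallest cohort on which all three
endpoints — patch validation accuracy, held-out slide accuracy, stitched
dice — are stable across seeds; they are the package's study conditions,
not tuning knobs.

## Known limitations

* The engine is single-threaded base R; full-resolution (256-px input,
  depth-4, 64-filter) U-Net training is configurable but not practical —
  the presets above are the supported regime.
* Probabilities from the lightly trained patch classifier are soft
  (rarely outside 0.2–0.8), so the extreme N_p bands (> 0.95) are
  typically zero on synthetic runs; the features still separate the
  classes through the location statistics.
* The slide-level booster is fit on tens of slides; its importance
  rankings on such cohorts are noisy, and exactly complementary feature
  pairs (normal vs tumor statistics) split credit arbitrarily unless
  column subsampling is enabled.
* `rasterize_mask` uses even-odd filling per polygon and union across
  polygons; self-intersecting annotation polygons are therefore
  interpreted even-odd, not by winding number.
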