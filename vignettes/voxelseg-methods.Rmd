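---
title: "voxelseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxelseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`voxelseg` labels every voxel of a 3D greyscale volume with a semantic
class, learning from a sparse set of manually annotated slices. This
vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, the numerical conventions, what
the synthetic generators do and do not emulate, and the design choices
made where the method left room.

## The segmentation model

The segmenter is a per-voxel classifier over hand-crafted texture
features. For `N >= 2` labels (one of which plays the role of "anything
else"), a classifier maps each voxel's feature vector to a label id. The
feature vector concatenates four parts:

* **intensity** (1 value): the voxel's scale-0 value, rescaled to the unit
  interval by the volume's recorded global bounds. This is a proxy for
  material density.
* **short-range histogram** (`k1` values): counts of the `(2r1+1)^3` cube
  around the voxel at scale 0, binned into `k1` linearly spaced bins over
  the recorded global intensity range, then divided by the cube size.
* **long-range histogram** (`k2` values): the same statistic with its own
  radius at pyramid scale `s2` (0–2).
* **LBP-TOP** (30 values): on each of the three orthogonal planes through
  the voxel (xy, yz, xz) at scale `s3`, every voxel of the plane gets a
  uniform rotation-invariant local binary pattern code from its eight
  in-plane neighbours at radius 1, and the codes inside the in-plane
  `(2r3+1)^2` window are histogrammed. There are exactly 10 possible
  codes, so the block is `3 x 10` counts, divided by the window size.

Histograms see the *distribution* of density in a neighbourhood; LBP sees
its *arrangement* — it is deliberately insensitive to absolute intensity
but sensitive to where values sit relative to each other. The test suite
contains a fixture (`make_lbp_discriminable_pair()`) in which histograms
provably carry zero class information while LBP separates the classes
essentially perfectly; see below.

### Scales: the pyramid

Scale `s` is the volume blurred with a 3D Gaussian and decimated by
`2^s` along each axis (indices `0, 2^s, 2*2^s, ...` are kept, so the level
shape is `floor(shape / 2^s)`). Coordinates map between scales by floor
division: a scale-s voxel covers a `2^s` cube at scale 0. Conventions the
method itself does not fix, pinned here:

* **Blur width.** `sigma(s) = 2^(s-1)` scale-0 voxels for `s >= 1`,
  truncated at 4 sigma — anti-aliasing width proportional to the
  decimation factor. It is a `sigma_rule` argument of `build_pyramid()`
  for sensitivity analyses.
* **Blur input.** Every level is blurred from the scale-0 data, not
  cumulatively level-to-level; the two differ only slightly and a single
  definition keeps the cache reproducible.
* **Boundaries.** Reflect (edge-repeating) padding, which avoids
  darkening at the volume faces; a constant volume is constant at every
  scale to float precision.

### Neighbourhoods, borders and bins

All neighbourhoods use edge-replicated (clamped) indexing, so every voxel
— including corner voxels — has a full-size neighbourhood and every
histogram sums to exactly `(2r+1)^3` (or `(2r+1)^2` in-plane). This keeps
count-conservation testable everywhere and avoids special-casing borders.

Histogram bins are linearly spaced over the *recorded scale-0 global
range* of the training volume, shared by all scales and stored in the
trained model, so inference bins intensities exactly as training did.
Blurred values cannot leave that range (blurring is a convex combination
and reflect padding introduces no new values), but clamping into the end
bins guards the degenerate cases anyway. A constant volume (zero range)
widens its bin range by ±0.5 so edges stay strictly increasing.

The LBP conventions the method leaves open are pinned in one place
(`lbp_code()`): ties `neighbour == centre` count as bit 1; the ring is
traversed clockwise starting directly above the centre. Both choices are
immaterial to the rotation-invariance property (verified exhaustively over
all 256 patterns × 8 rotations) and to the code count of 10.

### Incremental histograms

Computing each cube histogram independently costs `O(r^3)` per voxel. The
package's sliding path exploits the overlap of adjacent neighbourhoods:
moving the centre one step along z subtracts the counts of the departing
xy-plane of the cube and adds the arriving one — `O(r^2)` per voxel, with
one full `O(r^3)` count per (y, x) column to start. Clamped indexing
composes cleanly with the increment (the clamped window multisets still
differ by exactly one departing and one arriving plane), so the
incremental and naive paths agree bit-for-bit; the acceptance suite
checks this voxel-for-voxel across radii 1–4, bin counts 8–32 and scales
0–1, on awkward non-divisible shapes too. The same idea applies in 2D to
the LBP code windows.

### Slabs and memory

`segment_volume()` walks the volume in z-slabs: per-voxel features and
predictions are only materialised for one slab at a time, and the output
is identical for every slab thickness (tested for thicknesses 1, 4 and
nz). Pyramid levels themselves are held in memory — the memory hazard at
target scale is the feature matrix (tens of values per voxel), not the
volume copy, and slabbing removes exactly that hazard.

## Classifiers

**Random forest** — CART trees with Gini impurity splits, maximum depth
16, no leaf-count limit, `floor(sqrt(p))` features considered per split,
bootstrap resampling; 16/32/64 trees. The per-*split* feature subsampling
follows the reference implementation the method's description points at,
although the description says "per tree". Scores are the average of leaf
class distributions; ties break to the lowest label id. Fitted forests
are plain R lists of matrices: serialisation round-trips bit-exactly.

**Neural network** — two hidden layers (32–256 units each), leaky ReLU
(slope 0.01), softmax output with cross-entropy loss (the loss is not
stated by the method description; cross-entropy is the standard multiclass
choice and is flagged as an assumption), Adam at learning rate `1e-3`,
minibatches of 4–64, inverted dropout (rate 0–0.5), weights initialised
`N(0, stddev^2)` with zero biases. Early stopping is named but not
specified by the method: here it is at most 100 epochs, patience 5 on the
validation cross-entropy of an internal stratified 20% holdout, best
weights restored (the restored loss is asserted `<=` the final loss in the
tests).

Both classifiers are deterministic given their seed. Class imbalance is
not reweighted: the sampling protocol draws balanced per-label samples,
which is also why plain accuracy is a fair model-selection score.

## The two-stage hyperparameter search

The joint space is: short-range radius 1–8 and bins {8, 16, 32};
long-range scale 0–2, radius 1–32, bins {8, 16, 32}; LBP scale 0–2 and
radius 1–32; plus the classifier block (trees {16, 32, 64}; or layer
sizes, dropout, init stddev, minibatch). The search:

1. **Global phase**: up to `I_g` iterations, each drawing every variable
   independently and uniformly.
2. **Local phase**: up to `I_l` iterations mutating exactly one variable
   (uniform over variables, new value uniform over the variable's values
   excluding the current one) of the best configuration so far —
   stochastic hill climbing.

Visited configurations are never re-evaluated. A phase ends early when
`t` seconds pass *inside the hunt for a not-yet-visited configuration*;
the timer resets each iteration. (The alternative reading — a timer from
phase start — would abort any phase whose model training takes longer
than `t`, which contradicts the stated budgets, so it is rejected.) The
clock is injectable, which is how the degenerate-space behaviour
(evaluate one configuration, then time out) is tested without waiting.

Continuous variables are discretised so that the visited-set test is
meaningful equality: dropout on a 0.05 grid, init stddev on a 16-point
log-spaced grid (its range spans four decades, so uniform-on-log).
Accuracy ties keep the earlier configuration (strict improvement only).
Candidates are scored by plain accuracy on a balanced per-label validation
sample; after the search, the final model is retrained on the full
training set with the winning configuration, with fixed seeds.

## Pipeline protocol

Annotated slices are split 60/20/20 into train/validation/test *by slice*,
never by voxel — neighbouring voxels are heavily correlated, and a voxel
split would leak. Set sizes use largest-remainder rounding with ties to
the earlier set (so 5 slices split 3/1/1). Training voxels are sampled per
label, uniformly without replacement, capped per label; the ignore
sentinel (255) marks unannotated voxels and is never sampled and never
scored. "Unlabelled" in a label map is different: it is an ordinary,
trainable "anything else" class.

Evaluation reports per-label IoU (as a percentage; blank/NA for labels
absent from both truth and prediction), the confusion matrix over
non-ignored test voxels, each label's share of test voxels, and two
"overall" numbers reported distinctly because the method's own summary
metric is ambiguous: voxel accuracy (fraction correct) and micro-averaged
IoU (`correct / (2*total - correct)`). They coincide only in the
all-correct limit.

## Synthetic fixtures: what they do and do not establish

`make_textured_volume()` builds labelled phantoms from region geometries
(spheres, shells, half-spaces, a remainder) and intensity models (IID
Gaussian; smoothed noise with a correlation length; striped square waves
with noise). Intensities are generated in the unit interval and quantised
to 16 bits so the integer I/O path is exercised. Generators are pure
functions of `(spec, shape, seed)`.

The default phantom (`default_phantom()`, 64^3) nests a bright Gaussian
"bone" core, a smoothed-noise "soft tissue" shell and a striped
"wrapping" background, with region means separated by many noise standard
deviations. This emulates the *protocol* of a real study — sparse slice
annotation, slice-level splits, per-label sampling, blocked full-volume
inference — at desk scale. It does not emulate real tomography physics:
no phase-contrast fringes, ring artefacts, beam hardening, partial-volume
mixing at material boundaries, or lossy-codec noise. A green recovery
test therefore establishes that the pipeline machinery is correct and
that the features separate textures that differ the way the phantom's
do — not that any particular accuracy will be met on real scans.

`make_lbp_discriminable_pair()` is built to witness the reason LBP is in
the feature set at all. Designing it exposed a subtlety worth recording:
when training and test voxels come from the *same* finite volume, a
forest can reach well above chance on histogram features against any
volume-wide deterministic texture, by memorising position-specific
window-count signatures — several natural designs ("isotropic noise vs
stripes", orientation pairs with global or per-column phases) measured
0.78–0.84 this way during design. The shipped construction closes that
route with an exact symmetry: the lower z-half carries stripes along y
(random phase per stripe column); the upper half is the *mirrored
transpose image* under `(z, y, x) -> (nz-1-z, x, y)`. That involution
swaps the labels, maps faces to faces, and maps every cubic neighbourhood
to a transposed one with an identical value multiset — so intensity,
every cube histogram at every radius and scale, and the (rotation- and
reflection-invariant) xy-plane LBP histogram are *exactly equal* for each
voxel and its opposite-class twin. Any deterministic classifier on those
features scores exactly 1/2 on the full population; only the yz/xz LBP
blocks, which the transpose exchanges, can separate the regions. The
acceptance criterion (histogram-only accuracy <= 0.6, with-LBP >= 0.9)
holds by construction rather than by tuning.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(z, y, x)` throughout the public API; z-ranges
  are half-open. Arrays are stored z-fastest.
* Probability rows sum to 1 within 1e-6; argmax ties go to the lowest id.
* A single-label training set is allowed and yields a constant predictor;
  an empty one is an error.
* TIFF support is a minimal built-in baseline codec (uncompressed
  greyscale 8/16-bit, striped, multi-page, both byte orders on read) —
  the environment offers no R TIFF reader — and is cross-validated
  against an independent Python TIFF implementation in the tests. Lossy
  formats are deliberately out of scope: users convert to TIFF/HDF5.
* The ignore id is fixed at 255, which caps label maps at 254 classes.

## Known limitations

* The neural network trains in interpreted R; it is fine at the
  package's sample sizes (10^3–10^5 voxels, tens of features) but is not
  the tool for multi-million-sample training runs.
* No morphological or Markov-random-field cleanup of the label volume is
  included; segmentation noise at label boundaries is left as-is.
* Pyramid levels are held in memory; volumes must fit in RAM once (the
  slab machinery bounds the *feature* memory, which is the dominant
  term).
* The hyperparameter search evaluates candidates sequentially; there is
  no parallel or multi-fidelity scheduling.
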