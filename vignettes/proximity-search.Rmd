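---
title: "Decision-path proximity search for histopathology photomicrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-path proximity search for histopathology photomicrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pathologists who share photomicrographs — often smartphone pictures of a
microscope field, with free-text commentary and hashtags — need two things
from a computational assistant: a calibrated guess at the disease state
(nontumor, low grade, or malignant) and, more usefully, *similar past cases*
to anchor a discussion. `histoprox` implements both around a single model: a
random forest disease-state classifier whose internal decision paths are
repurposed as a similarity metric. Two cases are similar to the degree that
the forest's trees route them through identical sequences of decisions to
the same leaf; with the default 1000 trees the similarity of a pair is an
integer in 0..1000, maximal for a case against itself.

Everything around that core is the supporting cast of a realistic pipeline:
image standardization, a fixed bank of hand-engineered visual features, a
patch-level encoder with a sum-pooled set representation, weak-supervision
labeling from hashtags and keywords, clinical covariates with honest
missingness, three sanity checks per search, permutation feature importance,
and the evaluation protocol (ten-fold and leave-one-pathologist-out
cross-validation, weighted AUROC, precision@k, permutation null, rank-sum
comparisons). A synthetic-corpus generator stands in for real social-media
data so every stage can be exercised reproducibly at desk scale.

## Image standardization and the 21-patch grid

Photomicrographs arrive at arbitrary sizes. Each image is gray-world
white-balanced (each channel rescaled by global-mean/channel-mean, clipped
to [0, 255]) — the simplest correction for the blue cast of under-lit
microscope photos — then bilinearly rescaled so its shortest side is exactly
512 px (long side rounded half-up) and center-cropped to 512 × 512. The crop
feeds the hand-engineered features; the full rescaled image feeds the patch
grid.

The set representation samples 224 × 224 patches at a 5 × 5 lattice of
offsets, rows at `linspace(0, H − 224, 5)` and columns at
`linspace(0, W − 224, 5)`: wider images get larger column strides, i.e. less
horizontal overlap. Four of the 25 slots are not evaluated, leaving 21
patches. We drop the four *interior diagonal* slots (2,2), (2,4), (4,2),
(4,4) rather than the corners: at a 512-px minimum side the lattice stride
is 72 px < 224 px, so every interior slot is fully covered by its neighbours
while each corner slot is the *only* slot covering its corner region.
Dropping interior slots therefore preserves the guarantee that the 21
patches jointly cover the whole image, for every valid geometry; dropping
corners would leave the four 72 × 72 corner regions unobserved. The four
unevaluated tiles are exactly the ones imputed in the 5 × 5 heatmaps, and
each has all four of its lattice neighbours evaluated.

Training-time augmentation applies, in fixed order: right-angle rotation,
small rotations up to ±15° with reflect padding, horizontal/vertical flips,
zoom in [0.9, 1.1], brightness gain in [0.9, 1.1], Gaussian noise with
σ = 2.5 on the 8-bit scale, and Mixup with Beta(0.2, 0.2) weights. The
magnitudes are conventional defaults, pinned in `augment_config()` for
reproducibility; determinism is the caller's responsibility via the RNG
state.

## The 2412-dimensional hand-engineered bank

`hand_features()` concatenates, in a fixed documented order
(`feature_layout()`):

| block | length | content |
|---|---|---|
| `rgb_hist` | 768 | three 256-bin channel histograms, each L1-normalized |
| `hsv_hist` | 768 | the same in HSV space |
| `gray_hist` | 256 | luminance histogram |
| `lbp_pyramid` | 324 | rotation-invariant uniform LBP, (P,R) ∈ {(8,1), (16,2), (24,3)} → 10+18+26 bins, over a 6-level half-resolution pyramid |
| `sobel_orient` | 216 | 36-bin magnitude-weighted gradient-orientation histograms over the same pyramid |
| `glcm` | 52 | 13 gray-level co-occurrence (Haralick) statistics × 4 offsets at 32 gray levels |
| `hu_moments` | 7 | log-scaled moment invariants |
| `channel_stats` | 21 | mean/sd/entropy for R, G, B, H, S, V, gray |

The lengths sum to exactly 2412. An earlier draft of the table also carried
a Sobel-magnitude histogram; its bin count is the designated slack absorber
for the 2412 total, and the arithmetic leaves it at zero bins, so the block
is absent. The LBP pyramid gives scale- and color-invariant texture — the
dominant signal for disease state — while the histograms carry stain
chemistry and the co-occurrence block carries second-order texture.

One numerical choice deserves a note: LBP compares each interpolated
neighbour against its center pixel with a tolerance of 10⁻⁶ gray levels.
Bilinear interpolation of a constant region reproduces the center value only
up to floating-point rounding; without the tolerance, flat regions would
flip between the "flat" code and spurious non-uniform codes under a global
intensity shift, breaking the monotone-shift invariance that makes LBP
useful.

## SIFT clusters

Nuclear-scale blob structure is summarized separately: a
difference-of-Gaussian detector (3 octaves, 3 scales, base σ 1.6) finds up
to 200 keypoints per crop, each described by the classic 4 × 4 × 8
gradient-orientation descriptor (128-d, clipped at 0.2 and renormalized). A
k-means vocabulary of k = 5 visual words is fitted *on training-fold crops
only* — refitted inside every cross-validation fold, so held-out
pathologists never influence it — with centroids ordered most-prevalent
first. Each crop is then a 5-bin L1-normalized bag of words (the zero vector
when featureless). Five words is deliberately coarse: the point is the few
dominant nuclear motifs, not a full codebook.

## The patch encoder and set representation

The encoder maps a 224 × 224 patch to (i) a 100-dimensional
approximately-binary feature vector and (ii) a 3-way softmax disease-state
activation. The desk-scale backbone is a fixed convolutional front end — the
patch is downsampled to 32 × 32, a small filter bank (smoothing,
horizontal/vertical Sobel, Laplacian) is applied, and responses plus raw
color are average-pooled on a 4 × 4 grid (112 dims, linear and bias-free so
a zero patch maps to zero) — followed by a trainable fully-connected
network: hidden ReLU layer (32 units), then the 100-unit head, then the
class head. The clinical covariate vector (tissue one-hot, or zeros when
missing, plus the marker bit) is concatenated into the head's input. Full
backpropagation through convolutions is deliberately out of scope for a
single-CPU package; the fixed filter bank carries the generic early-vision
features such a network would learn, and every interface contract (head
range, set bounds, determinism, pluggability) is identical, so a pretrained
2048-d backbone can be plugged in where available. `generic_backbone_stub()`
provides the deterministic stand-in for such a generic-vision backbone: a
seeded random projection of the same patch summary, labelled synthetic.

"Approximately binary" is achieved with a steep sigmoid, `sigmoid(τ·z)` with
τ = 4, plus a penalty λ·mean(x(1−x)) with λ = 0.01 added to the
cross-entropy; both are exposed in the constructor. Two initialization
details matter in practice: head-input weights are scaled down by 1/τ so the
steep sigmoid starts in its active region rather than saturated, and patch
summaries are standardized by training-set mean and standard deviation
(stored in the encoder). Without either, gradients through the saturated
head vanish and training stalls at chance.

Training minimizes cross-entropy on patch labels inherited from the image
label — weak labeling: a nontumor image's background patches are all
labelled nontumor — with the augmentations above and Mixup target mixing,
by minibatch gradient descent with momentum (defaults: 8 epochs, batch 32,
learning rate 0.05), single-threaded and bit-reproducible from the seed.

The image-level representation is the elementwise *sum* of the 21 per-patch
head vectors (`set_sum()`): order-invariant, size-invariant, each entry in
[0, 21]. The 2048-d generic block is pooled the same way.

## Covariates, weak labels, and missingness

Tissue type (ten canonical categories) and marker mention (whether the
discussion mentions an ancillary test such as IHC or a specific antibody)
are parsed from case text by editable plain-text rule tables: one rule per
line, `pattern TAB target TAB priority`, matched case-insensitively on word
boundaries. Hashtags are consulted before free text; each document (hashtag
set, post, each reply) votes for its highest-priority match, with multi-word
patterns outranking their substrings ("carcinoma in situ" beats
"carcinoma"); conflicts resolve by majority, then priority, then to missing.
The shipped tables (~130 rules) are a scaffold meant to be edited, not a
canonical medical lexicon.

Missing tissue is encoded honestly for each consumer: all-zeros for the
neural encoder, but *missing values* for the forest, which excludes them
from split-gain computation and routes them down a stored majority branch.

## The proximity forest

`train_forest()` is a classic Breiman forest — bootstrap resampling, Gini
splits, √d candidate features per node, unlimited depth, minimum leaf size
1 — written from scratch (C++ core) for one reason: decision-path proximity
needs per-tree leaf identities under *deterministic* missing-value routing,
which established forest packages do not expose. Missing values never enter
split-gain computation; at prediction a missing split feature follows the
branch that carried the majority of the node's observed training records
(ties left). Every record therefore follows exactly one root-to-leaf path,
`leaf_index()` is total and reproducible, and identical leaf ⇔ identical
decision sequence. Forests serialize to portable JSON with bit-identical
routing after reload.

Similarity, prediction, and interpretation all read off the same structure:

* `proximity(f, a, b)` — co-leaf count in 0..n_trees; symmetric;
  `proximity(x, x) = n_trees`; also reported normalized by n_trees.
* `predict_activations()` — per-class tree-vote fractions (sum to 1).
* `permutation_importance()` — mean decrease in held-out accuracy when a
  feature's values are shuffled; the ten tissue one-hot columns are shuffled
  jointly as one block, since they encode one clinical fact.
* `forest_ensemble()` / `uncertainty_check()` — three independently seeded
  members; the prediction margin (top class minus runner-up) is
  bootstrapped over trees, and a margin interval covering zero flags the
  prediction — and any search built on it — as uncertain. The
  bootstrap-over-trees construction is our choice of uncertainty statistic;
  it is cheap, seeded, and directly measures tree-level disagreement.

## Search and its three sanity checks

`build_index()` precomputes the corpus leaf table (n_records × n_trees per
member); `query_index()` ranks the corpus by proximity (summed across
ensemble members when present), ties broken by ascending corpus id, and
attaches three flags: (i) the uncertainty verdict; (ii) disagreement between
the forest's predicted class and a caller-supplied expected label — if the
classifier is wrong about the query, its similarity metric should not be
trusted either, because prediction and search are the same model; (iii)
whether a prediction heatmap was generated for human review. During
evaluation the query is excluded from its own corpus (leave-one-out
correctness); interactive queries may keep it.

Heatmaps evaluate the encoder on the 21 tiles of the 5 × 5 grid; the 4
unevaluated tiles are imputed with the per-class median of their 4 nearest
evaluated tiles (Euclidean distance on grid coordinates, row-major
tie-break), then each tile's class activations are renormalized to sum to 1.
Feature heatmaps do the same for a single head feature, without
renormalization.

## Evaluation protocol

Classification tasks use stratified ten-fold cross-validation, replicated
ten times with seeds 0..9; the summary metric is the one-vs-rest AUROC per
class (midrank Mann–Whitney statistic) weighted by class instance counts.
Search uses leave-one-pathologist-out cross-validation: all cases from one
contributor are held out, the forest (and any fold-fitted transform: SIFT
vocabulary, encoder) is trained on the rest, and each held-out case queries
the training corpus; precision@k (k = 1..10) is scored against true labels,
overall and per pathologist. This isolates contributor-specific staining,
lighting, and camera artifacts, which is exactly what the synthetic
generator's per-pathologist tints let you stress.

The chance model is a permutation null: identical pipeline, labels shuffled
before training only, evaluation labels untouched. Replicate sets are
compared with a two-tailed Wilcoxon rank-sum test — exact null distribution
when there are no ties and both samples have ≤ 12 replicates, otherwise a
normal approximation with tie and continuity corrections. We deliberately
expose both modes rather than chase any particular approximation's digits,
and fully tied samples return p = 1.

## The synthetic corpus

`generate_dataset()` renders a corpus whose *statistical* structure mirrors
the real problem while remaining fully seeded: stain palettes (H&E-like
pink/purple, IHC-like brown/blue, gray "other") modulated by a small
tissue-specific hue shift; elliptical "nuclei" whose density, size spread,
and eccentricity variance carry the class signal (defaults 100 / 225 / 400
blobs per image for nontumor / low grade / malignant, with increasing
pleomorphism); per-pathologist global tint and gain jitter (strength 0.05)
as a confounder; and case text generated by inverting the label rules, with
a configurable corruption rate. Class is deliberately carried by *texture*,
not color, so stain and pathologist tint act as confounders the
leave-one-pathologist-out protocol must overcome — and with the class signal
switched off and artifacts turned up, a forest can learn to predict the
pathologist but not the class, reproducing the artifact-leakage risk the
protocol exists to catch.

The default study conditions — 300 images, 10 pathologists, balanced
disease states, uniform tissues, 60/30/10 stain mix, seed 0 — are what the
test suite and the acceptance script run end to end; they were chosen once
as a realistic desk-scale corpus and are not tuned per experiment. Labels
are allocated by exact largest-remainder counts and the case order is
shuffled so corpus ids carry no class information (rank tie-breaks are by
id).

What the generator does *not* emulate: real nuclear morphology and tissue
architecture, stain variability within a palette, image compression
artifacts, multi-panel figures, or ambiguous diagnoses. Passing tests on
this corpus demonstrate that the machinery is correct and leakage-safe, and
that the protocol behaves as designed under a known signal; they do not
certify clinical performance on real photomicrographs.

## A known limitation: the permutation null under strong separability

On this synthetic corpus the permutation-null *search* precision does not
fall to the class prior, and this is a property of decision-path proximity
worth understanding rather than hiding. A forest grown to minimum leaf size
1 on shuffled labels still chooses data-adaptive splits — noise maximization
picks thresholds aligned with the feature distribution — so co-leafing
degenerates into an adaptive nearest-neighbour relation in feature space.
When classes are strongly separated in the features (as the generator's
texture gap makes them, by design, so that the recovery and stain criteria
are meaningful), a case's nearest neighbours share its class and null
precision stays far above prior; the same behaviour reproduces with an
established forest implementation used as a cross-check. A chance-level
null, as observed on real weakly-separable corpora, is therefore evidence
about the *data* (features only weakly aligned with class), not a guarantee
of the algorithm. The shuffled-label *classification accuracy* null, by
contrast, does sit at the prior here, because leaf majorities of shuffled
labels are uninformative. The acceptance suite computes both and reports
them as measured.

## Problem sizes and budgets

Defaults are sized for one CPU: hand features ≈ 0.7 s per image; a
1000-tree forest on 300 × 2423 features trains in ≈ 10–20 s; the full
leave-one-pathologist-out study (10 folds, 1000 trees each) plus its
permutation null and the stain task complete in roughly a quarter hour.
Encoder training in pipeline methods uses 5 patches per image and 4–8
epochs — enough to demonstrate learning and interpretability on the
synthetic signal.

## Worked example

```{r example}
library(histoprox)

man <- generate_dataset(synth_config(n_images = 60, n_pathologists = 5,
                                     seed = 1))
x <- fuse_features(hand = extract_hand_features(man),
                   cov  = extract_covariates(man))

forest <- train_forest(x, man$gold_disease, n_trees = 1000, seed = 0)
idx <- build_index(forest, x, ids = rownames(x))
q <- query_index(idx, x["case_0007", , drop = FALSE], k = 5,
                 exclude_id = "case_0007",
                 expected_label = man$gold_disease[7])
q
autoplot(q)

rep <- lopo_cv(x, man$gold_disease, man$pathologist_id,
               n_trees = 1000, seeds = 0)
rep
autoplot(rep)
```
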