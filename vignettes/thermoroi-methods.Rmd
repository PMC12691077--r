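---
title: "Illumination-adaptive ROI detection and temperature extraction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Illumination-adaptive ROI detection and temperature extraction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoroi)
```

## The problem

Rectal temperature (RT) is the reference indicator of health state in
dairy cows, but measuring it is invasive and stressful.  Infrared
thermography offers a contact-free alternative: skin sites that are thin
and richly vascularised ("thermal windows") track core temperature.  On
lactating cows the two most informative such sites are the lower udder
(LU) and the perianal area (AA); their surface temperatures correlate
strongly with RT, with a stable physiological gradient RT > AA > LU
(heat flows from the core outward, and the udder dissipates more heat
than the perianal skin).

Automating the measurement means finding the LU and AA regions on an RGB
frame that is co-registered with a radiometric temperature map, then
summarizing the temperatures inside each detected box.  Barn imagery
makes this hard in three specific ways, and the package's three main
components answer them one-to-one:

1. **Extreme illumination.** Frames are routinely under- or over-exposed.
   A grayscale gate routes each frame to a Retinex-based low-light
   enhancer or to CLAHE for overexposure (`enhance_auto()`).
2. **Confusing coat texture.** Holstein black-and-white patches defeat
   detectors that rely on colour and shape alone.  The detector is
   conditioned on a bank of five anatomical *text* categories whose
   descriptions chain the regions into a spatial structure
   (LU - hind legs - hind quarters, the latter containing RU and AA), so
   the model can exploit relative position, not just local appearance
   (`load_text_bank()`, `edc_forward()`).
3. **Deformable, centre-symmetric regions.** The udder deforms with
   posture; the anal region is centre-symmetric.  Training uses a
   task-alignment metric, Gaussian soft-constrained centre sampling and
   a hybrid CIoU/GIoU regression loss (`assign_targets()`,
   `hybrid_iou_loss()`).

## The illumination gate

Luminance is the BT.601 weighted sum `0.299 R + 0.587 G + 0.114 B`, kept
real-valued.  With mu the mean luminance over all pixels, the regime is

* low light when `mu < 60`,
* overexposed when `mu >= 150` (this test precedes the default, so
  exactly 150 is overexposed),
* normal otherwise (exactly 60 is normal).

Both thresholds are configurable (`enhancement.t_low`, `t_high`), and the
gate is exhaustive: every mu in [0, 255] maps to exactly one label.

## Low-light path: Retinex decomposition

A low-light frame is modelled as `I = R * L`: a reflectance map `R`
(intrinsic colour/texture, per channel) times an illumination map `L`
(shared across channels).  The decomposition is computed in two steps.

**Initialization.**  The initial illumination is the per-pixel maximum
over the RGB channels, floored at 1e-4; the initial reflectance is the
input divided by it.  This is the closed-form minimizer family of the
initializer objective (the max channel bounds every channel, so the
product reconstructs the input exactly wherever the floor is inactive).
The package uses this classical initializer rather than a trained
network: it preserves the physical model and is exactly testable.

**Refinement.**  The decomposition is refined by `stages` (default 3)
rounds of block-coordinate descent on the penalized energy

    E(P, Q, R, L) = ||I - P.R||^2 + alpha phi(R) + beta psi(L)
                    + gamma ||P - Q||^2 + lambda ||Q - L||^2

with `P`, `Q` auxiliary illumination variables and `phi`, `psi` quadratic
total-variation-style smoothness penalties (sums of squared forward
differences).  `P` and `Q` have exact per-pixel minimizers; `R` and `L`
take a few gradient steps with step sizes below the inverse Lipschitz
constants of their convex quadratic sub-objectives (`1/(2 max(P^2) +
16 alpha)` and `1/(16 beta + 2 lambda)`; the 4-neighbour grid Laplacian
has spectral norm at most 8).  Every update is therefore non-increasing
in E, which the tests assert stage by stage.  Defaults
(`mu_init = 0.05`, `alpha = 0.001`, `beta = 0.01`, `gamma = lambda =
0.1`, `T = 3`) keep regularization light and the stage count comparable
to a shallow unfolding; all are configurable.

**Adjustment.**  The refined illumination is brightened as `L^omega`
with `omega = 0.5` by default — a gamma map standing in for a learned
adjustment operator; it is monotone, fixes 1, and guarantees the output
`R * L^omega` is at least as bright as the reconstruction since
`L^omega >= L` on (0, 1].  The enhanced image is `R * L^omega` rescaled
to 8 bits.

## Overexposure path: CLAHE on the Lab luminance

The frame is converted to Lab (D65 white point; L rescaled to [0, 255]
so it can be histogrammed as an 8-bit channel).  Only L is modified; the
a, b chrominance planes pass through untouched, which preserves hue.

The L plane is split into a `grid_rows x grid_cols` tile grid (default
8 x 8; when the image size is not divisible, the last row/column of
tiles absorbs the remainder).  Each tile's 256-bin histogram is clipped
at `ceiling(clip_limit * tile_pixels / bins)` with `clip_limit = 3.0`,
and the clipped mass is redistributed uniformly; the integer remainder
goes one count each to the lowest-index bins, and redistribution repeats
until the cap holds, so the total mass is conserved exactly.  The
mapping of each tile is its normalized CDF scaled to 0-255.  Output
pixels blend the mappings of their up-to-four neighbouring tiles with
bilinear weights in the distance to the tile centres; the weights are
non-negative, sum to one, and degenerate to a single tile at tile
centres and outside the outermost centres.  With a single tile and an
unbounded clip the procedure reduces to plain global histogram
equalization, which the tests exploit as an independent oracle.

The clip count is derived from `clip_limit` only.  A fixed absolute
pixel frequency for the cap (sometimes quoted as 3600 for this
configuration) is not consistent with `clip_limit = 3` at 8 x 8 tiles
and 256 bins on 640 x 480 frames (a tile of 4800 pixels gives a cap of
57); the package treats `clip_limit` as authoritative and exposes both
knobs.

## The text prior

The five categories (LU, AA, RU, hind legs, hind quarters) with their
descriptions are data, not code: a JSON bank, shipped as
`textbank_default.json`, validated on load (unique known categories, at
least one ROI flag; the default flags exactly LU and AA).  The spatial
chain lives in the description wording.

No specific pretrained text encoder is mandated anywhere, so the package
ships a deterministic hashing bag-of-words encoder: each lowercased
token is hashed (with a seed) to a pseudo-normal vector; the sentence
embedding is the token mean, L2-normalized.  This keeps the repository
download-free and every test bit-reproducible.  Any encoder producing a
fixed-dimension vector per entry can be substituted; the default
dimension is 64.  The hashing embeddings of the five descriptions are
strongly correlated (cosines around 0.4-0.7, since the descriptions
share anatomical vocabulary); the detection head compensates with a
fixed logit temperature (below).

## Detector core

`edc_forward()` implements the text-guided modulation block:

1. attention refinement `X' = X (x) A_S (x) A_C`, with `A_S` the sigmoid
   of the channel mean (one weight per position) and `A_C` the sigmoid of
   the spatial mean (one weight per channel);
2. four text-derived modulation parameters — global scale `gs`, global
   shift `gb`, channel-wise scale `cs`, channel-wise shift `cb` — from a
   one-hidden-layer GELU MLP over the pooled text vector, applied as
   `X^ = X' gs cs + gb + cb` (the shifts add, they do not multiply);
3. `Y = X + GELU(layer_norm(X^))`, layer norm over channels per
   position, no learned affine.

The MLP output layer is zero-initialized, so the whole block is exactly
the identity at initialization — a clean test anchor and a stable start
for training.  `db_fuse()` is the learnable-weight fusion node:
`O = sum_i w_i I_i / (eps + sum_j w_j)` with `w_i = max(raw_i, 0)` and
`eps = 1e-4`, a convex combination up to the epsilon slack.

The miniature head that exercises these blocks end to end is
deliberately small and CPU-trainable; it is not a reproduction of any
full-scale backbone.  Fixed (untrained) pooled features are computed at
stride 4 and stride 8 over the frame: per-cell RGB means, the gray
standard deviation, intra-cell chroma (R-G) quadrant means, directional
chroma context at offsets of one and two cells plus directional
luminance context at one cell (region boundaries on a black-and-white
coat are chroma edges, and the offset context lets the regressor see
edges from inside a region), and normalized cell coordinates — 22
channels.  Features are standardized per image by their own per-channel
moments, which absorbs the global photometric shifts left over from the
three illumination regimes and their enhancement paths.  The coarse map
is upsampled to the fine anchor grid and fused with `db_fuse()`; the
classification branch applies `edc_forward()` conditioned on the pooled
bank embedding; the box branch reads the pre-modulation features, so
text changes can never move box geometry.
Per-category scores are `sigmoid(tau * <e, t_k>)` with `e` the anchor's
visual embedding (a linear map of the EDC output), `t_k` the category's
pooled unit-norm text embedding and `tau = 4` a fixed logit temperature
that compensates for the high cosine similarity between the hashing
embeddings.  Boxes decode as exponential left/top/right/bottom distances
from the anchor point.  Inference keeps detections above a 0.25 score
and applies class-wise greedy NMS at IoU 0.5 (the YOLO-family
convention; no inference thresholds are mandated elsewhere).

## Training strategy

Positive samples come from the task-aligned assigner.  For anchor i and
ground truth j the alignment is `A_ij = p_ij^alpha * u_ij^beta`
(defaults alpha = 1, beta = 6, the task-aligned-assignment convention)
where `p` is the anchor's current score for j's category and `u` the IoU
of the anchor's current box with j.  The Gaussian centre weight is
`w_ij = exp(-d^2 / sigma^2)` with `d` the anchor-to-centre distance
normalized by half the target's diagonal and sigma = 0.5.  The combined
metric is the product `m = A * w` (the two mechanisms are published
separately; the product is this package's composition choice — it keeps
both scores in (0, 1] and lets either veto a candidate).  Each target
takes its top-k anchors by `m` (k = 10, clipped to the anchor count;
zero-metric candidates never become positives); an anchor claimed by
several targets goes to the larger metric, ties broken by larger IoU
then lower target index.

The regression loss blends the two IoU generalizations,
`lambda CIoU + (1 - lambda) GIoU` with lambda = 0.5 by default.  Since
that blend is a similarity, the minimized loss is the complement
`1 - (lambda CIoU + (1 - lambda) GIoU)` — zero exactly for a perfect
box.  The exponent in the Gaussian weight is `d^2 / sigma^2` exactly as
stated (not `d^2 / (2 sigma^2)`).

Training is full-batch Adam with a step decay (the learning rate drops
tenfold over the final 30% of epochs, which stabilizes the otherwise
oscillation-prone constant-rate trajectory).  Gradients are analytic
through the heads, the layer norm and GELU of the EDC block, and the
modulation MLP's output layer; the two fusion weights use exact central
finite differences on the epoch loss (two scalars, so four extra
forward passes); the hybrid-loss gradient with respect to the four box
distances is a central finite difference (the loss is piecewise-smooth
and cheap).  The hidden layer of the modulation MLP stays at its random
initialization: with a single bank-level text vector it is an arbitrary
fixed basis, and training its output layer spans the same function
class.  Classification is binary cross-entropy over all anchors and
categories with positives up-weighted 8x.  The regression term is
macro-balanced across categories — every category's positives carry
equal total weight — because the auxiliary categories (hind legs, hind
quarters) contribute several times more positive anchors than the two
ROIs and would otherwise dominate the shared regressor at the ROIs'
expense.  GELU uses the standard tanh approximation throughout.

## Evaluation

Matching is greedy in descending confidence: a detection claims the
unmatched same-class ground truth with the highest IoU at or above the
threshold (0.5), otherwise it is a false positive; any unmatched ground
truth counts as a miss, whether the region was undetected or detected as
another category.  `P = 100 TP/(TP+FP)` (defined as 0 when there are no
detections), `R = 100 TP/(TP+FN)`.  AP uses all-point interpolation (the
precision envelope integrated over recall increments), which matches the
integral definition; mAP50 averages the defined per-class APs, and by
default only the two ROI classes are evaluated, mirroring
two-class inference accounting.  A class with no ground truth has no
defined AP and is excluded rather than zero-filled.

## ROI temperatures

A pixel belongs to a box when its centre falls in the half-open
rectangle `[x1, x2) x [y1, y2)` — deterministic and
resolution-consistent.  The extraction reports TMax, TMin and Tavg over
member pixels; TMax is the body-surface characteristic of choice because
cow skin is warmer than every background surface, so the within-box
maximum is robust to the box containing non-ROI pixels.  Extraction uses
the detection box directly; finer segmentation inside the box is out of
scope.  Error statistics against per-animal references are absolute
maximum/minimum/mean, with the signed mean kept as a secondary field
because detection errors bias extraction toward slight underestimation.
Spearman rank correlation (average ranks on ties) drives ROI selection:
the k sites most correlated with RT, ties broken alphabetically.

## The synthetic scene generator

All tests run on seeded synthetic scenes; no external data is needed.
A scene is a body ellipse textured with thresholded Gaussian-smoothed
noise (emulating random black-and-white patches), viewed from the side
or the rear.  Region boxes follow the text-bank layout: rear views place
AA above RU, hind legs flanking RU, and hind quarters enclosing them;
side views place LU adjacent to a hind leg with RU absent.  Each
annotated region except the hind-quarters frame carries a consistent
colour signature (pink udder skin, dark perianal skin, lighter rear
udder, dark limbs) so that a miniature linear-head detector can learn
the anatomy from colour and layout; real coats are far harder, and
passing tests on these scenes demonstrates that the training machinery
works, not that the miniature head would survive a barn.

Temperatures are coupled per animal: RT ~ Normal(38.7, 0.35) degC, AA at
RT - 1.3, LU at RT - 2.3 (each with 0.2 degC noise, clamped into the
field ranges LU [35.2, 37.5] and AA [36.9, 38.5]), body and background
drawn below them, plus 0.1 degC pixel noise by default — so RT > AA > LU
holds by construction for essentially every animal, with offsets matched
to published per-animal tables.  The per-animal draws happen before
rendering, so two scenes generated from the same seed with different
views describe the same animal — that is how the AA > LU gradient is
checked across paired rear/side scenes.  The RGB luminance is rescaled
iteratively until the requested illumination regime band is hit (mean
gray below 60, in [60, 150), or at least 150), and generation fails
loudly if the band cannot be reached.  Dataset generation splits scenes
6:2:2 into train/validation/test and writes PNG images, range-normalized
float TIFF radiometric maps, YOLO and COCO annotations and a manifest of
per-scene seeds that allows exact regeneration.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use scenes of 160 x 120 pixels
(a quarter of the native 640 x 480 sensor resolution) and a 200-scene
dataset split 6:2:2 for the end-to-end training demonstration, with the
miniature head trained for 250 full-batch epochs (a few minutes on one
CPU core); property suites use 1000-instance randomized batteries for
the assigner and the temperature extraction and 100-image batteries for
the enhancement energies.  These sizes were chosen so the whole suite reproduces the
package's claims on a single CPU core in minutes while leaving every
algorithmic path exercised; nothing in the implementation depends on
them.

## Known limitations

* The Retinex refinement is a classical block-coordinate solver, not a
  trained unfolding network; it inherits the model's physics but not a
  learned prior, so its enhancement quality on real low-light frames is
  below the learned version it stands in for.
* The illumination adjustment `L^omega` is a fixed gamma map; a learned
  adjustment operator with the same interface can replace it.
* The hashing text encoder carries no semantics: two descriptions are
  similar only through shared tokens.  The text prior therefore acts as
  a structured conditioning vector, not as language understanding.
* The miniature detector's features are hand-pooled statistics with a
  small receptive field; it is sized to validate the training machinery
  on synthetic scenes and is not a field-ready cow detector.
* TIFF radiometric storage is normalized to the instrument range
  [-20, 250] degC (float TIFF readers expect [0, 1] samples); CSV grids
  store exact degC values.
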