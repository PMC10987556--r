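---
title: "Detecting finger-joint regions and mTSS special findings with a two-detector ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting finger-joint regions and mTSS special findings with a two-detector ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(handjoint)
```

## The problem

Radiographic scoring of rheumatoid arthritis with the modified total Sharp
score (mTSS) starts by locating every proximal interphalangeal (PIP), thumb
interphalangeal (IP) and metacarpophalangeal (MP) joint on a both-hands
radiograph — 20 joints per image — and flagging the high-scoring *special
findings*: ankylosis (bony fusion of the joint space) and
subluxation/dislocation (partial or complete loss of articular contact,
pooled into one label; the thumb IP carries no subluxation annotation, so
that task covers 18 joints). `handjoint` implements the detection stage as a
two-detector ensemble of anchor-box ("multibox") convolutional detectors:
one trained for the ankylosis task, one for the subluxation task, whose
box sets are fused into a single 20-joint prediction carrying both labels.

## Detector model

Each detector is a fully convolutional network that, for every *default
box* (anchor) $d$ of a pre-placed grid, emits three class logits
(finding present / finding absent / background) and four offsets
$(t_{cx}, t_{cy}, t_w, t_h)$ relative to $d$:

$$t_{cx} = \frac{g_{cx} - d_{cx}}{d_w},\quad
  t_{cy} = \frac{g_{cy} - d_{cy}}{d_h},\quad
  t_w = \log\frac{g_w}{d_w},\quad
  t_h = \log\frac{g_h}{d_h},$$

with `decode_boxes()` the exact inverse of `encode_boxes()`. Training
minimises the combined multibox objective

$$L = \frac{1}{N}\left(L_{conf} + L_{loc}\right),$$

where $N$ is the number of default boxes matched to ground truth,
$L_{loc}$ is the smooth-L1 penalty on the offsets of matched boxes and
$L_{conf}$ is softmax cross-entropy over matched boxes plus the hardest
negatives at a 3:1 negative:positive ratio. Two conventions deserve note
because the source formulation leaves them open: the printed combined loss
carries a stray leading minus sign and normalises only the confidence term,
which would reward large confidence loss; we adopt the conventional
$(L_{conf}+L_{loc})/N$ form consistent with the multibox design the method
builds on. Hard negative mining is likewise unstated; without it the
background class (hundreds of anchors against a handful of positives)
swamps the gradient, so the standard 3:1 ratio is used. Matching uses the
standard rule: an anchor is positive when its best IoU against the ground
truth reaches 0.5, and every ground-truth box additionally claims its
argmax-IoU anchor.

Two backbone configurations exist behind one engine. The reference layout
is the classic 300×300, six-source-map configuration whose default-box grid
(8732 boxes) ships as `grid_config_reference()`. The configuration that is
actually trained and exercised throughout the tests is the desk-scale
`detector_config_tiny()`: a 64×64 window, four 3×3 convolution blocks with
max pooling, two source maps (8×8 and 4×4, 320 default boxes, box scales
0.3 and 0.55 of the window) and one 3×3 convolutional head per map.
Instantiating and training the VGG16-scale reference backbone in pure R is
not a sensible desk-scale exercise; the tiny configuration keeps every
architectural ingredient (multi-map anchors, shared backbone, per-map
heads, the same losses) at a size a CPU trains in minutes. Convolution
forward/backward passes are compiled (Rcpp/RcppArmadillo, im2col + BLAS);
a pure-R shift-and-multiply implementation of the same kernels is retained
and cross-checked in the tests, and all loss gradients are verified against
central finite differences.

Grayscale windows are replicated into three channels (the colour mapping
used upstream is unstated; channel replication is the neutral choice).
Training crops one window per annotated joint per epoch at a uniformly
random admissible position, and augments each crop with four independent
transforms at 50% probability each: intensity jitter (gain 0.8–1.2, offset
±0.1 — "colouring" is read as brightness/contrast jitter), crop-resize
(random 80–100% sub-window), rotation by a random multiple of 90° (exact
for boxes), and horizontal flip. The optimiser is Adam with
$\alpha = 0.001$, $\beta_1 = 0.9$, $\beta_2 = 0.999$ and weight decay
0.0005, batch size 16.

## Whole-image inference

A whole radiograph is scanned by a sliding window (300 px window, 150 px
stride at the operating point, after a 50% resize of the 2010×1670 source;
the tiny detector uses its 64 px window with a 32 px stride). Windows
start at origin 0 and advance by the stride while the origin lies inside
the image; pixels beyond the image are zero-padded, so the window union
covers every pixel and any joint box smaller than window − stride lies
fully inside at least one window. Per window, decoded boxes are translated
by the window origin; then per detector:

1. **Confidence filter** — keep detections with confidence strictly above
   `t_conf = 0.9`, where confidence is the maximum softmax probability over
   the two *finding* classes. Background is deliberately excluded: a box
   the model calls background with high probability must not reach top-M
   selection.
2. **NMS** — greedy non-maximum suppression at `t_iou1 = 0.15` (inclusive
   ≥, per the stated rule). The threshold is deliberately strict because
   finger-joint boxes barely overlap on a hand radiograph. Confidence ties
   keep the earlier box in scan order, for determinism.
3. **Top-M** — keep the `M` highest-confidence boxes, `M1 = 20` for the
   ankylosis detector and `M2 = 18` for subluxation.

## Ensemble merge

The two detectors' outputs `B1` and `B2` are fused: pairs with IoU ≥
`t_iou2 = 0.45` are taken to mark the same joint and merge into one
detection carrying both labels; unmatched boxes pass through with the
negative-class placeholder (probability 1 on finding-absent) for the task
that did not propose them; if `M1 + 1` or more candidates remain, the `M1`
most confident are kept (the cut fires only then — exactly `M1` candidates
pass untouched). Three details are the package's own, since the procedure
specifies labels but not geometry: the fused box keeps the geometry and
confidence of the higher-confidence member (ties favour the ankylosis
path) rather than averaging, so every reported box is one an actual
detector proposed; cross-detector matching is greedy in descending
combined confidence; and matching is one-to-one. This merge is what makes
the ensemble robust: a joint missed by one detector survives via the
other, which the tests exercise directly (dropout in one oracle detector,
the other complete — the fused detection rate stays 100%).

## Evaluation protocol

Predictions are matched to ground truth greedily by descending IoU,
one-to-one; a joint counts as detected when its matched IoU is strictly
above 0.45. Classification counts (TP/FP/TN/FN per finding task) are
accumulated **over detected joints only**: a missed joint is a detection
failure and does not enter the classification table. This decoupling
matters when comparing detection rates with classification counts — the
two tables have different denominators by design. Metrics are accuracy,
precision, recall, specificity and F-value per fold, with 0/0 ratios
reported as undefined (NA) and excluded from fold averages; averages are
unweighted means rounded half-up to two decimals, matching the reporting
convention. The shipped `reference_fold_counts()` — the published per-fold
counts of the original clinical five-fold study — reproduce that study's
printed precision/recall/F averages exactly under this arithmetic (0.81 /
0.78 / 0.78 for subluxation; 0.98 / 0.81 / 0.88 for ankylosis). One
printed value does not survive recomputation: the fold-averaged
specificities compute to ≈0.997, which rounds to 1.00, not the printed
0.99; the package asserts the metrics that do reproduce.

Five-fold splitting works at the patient level (both timepoints of a
patient stay in one fold — the published protocol is silent here, but
splitting a patient across train and test would leak geometry) and spreads
finding-positive patients as evenly as integer counts allow. The published
protocol reports 210 training and 50 test images from 260, which cannot be
a plain partition (5 × 50 = 250); the splitter therefore partitions into
five 52-image groups and trims each test set to `test_size = 50` by moving
deterministically chosen finding-negative patients of the group into that
fold's training set. `test_size` is exposed for exact-partition use.

## Synthetic phantoms

Clinical radiographs cannot ship with the package, so `generate_hand()`
renders a minimal both-hands phantom: ten finger columns of bright phalanx
segments (bone, intensity 0.75) over a soft-tissue band (0.35) on a dark
background (0.10), separated by darker joint-space gaps; additive Gaussian
noise (sd 0.03). Ankylosis is rendered as the gap ossified to bone
intensity; subluxation as a lateral shift of all segments distal to the
joint by 45% of the finger width (≥40% keeps the finding visually
unambiguous). Joint boxes are centred on the gaps at 1.6× the finger
width — comfortably under window − stride, so the tiling cover property
holds. Defaults mirror the study cohort: 1005×835 rasters (the
half-resolution source), 260 images as 130 patients × 2 timepoints with
flags shared within a patient and geometry drifting between timepoints,
and per-joint finding prevalences 157/5200 (ankylosis) and 60/4680
(subluxation). `phantom_params_small()` (320×256, 13 px fingers) is the
desk-scale preset matched to the tiny detector.

What the phantom does *not* model is exactly what passing tests cannot
show: real bone texture, erosions and joint-space narrowing, overlapping
or severely deformed joints, metal artefacts, and exposure variation.
Green pipeline tests demonstrate that the machinery — tiling, decoding,
NMS, fusion, bookkeeping — is correct, not that the tiny detector would
perform clinically. `oracle_detector()` makes that separation explicit: it
emits ground-truth boxes under controllable jitter, dropout and label
noise, so every inference-side stage is testable with known answers and
no training in the loop.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale sizes chosen as
the package's own operating points: the learning smoke test trains the
tiny ankylosis detector on 50 small phantoms for 20 epochs (a few minutes
on one CPU; the loss curve has flattened by then) and requires per-window
recall ≥ 0.9 at IoU > 0.45 on 10 held-out phantoms, evaluated with a 0.5
confidence filter — a partially trained desk-scale model does not reach
the saturated confidences the 0.9 operating threshold assumes of the fully
trained clinical model, and the property under test is localisation, not
calibration. Cohort arithmetic (5200/4680 annotations) is checked at the
full 260-image size with rendering disabled; the annotation stream is
drawn before rendering, so annotations are identical either way.

Other numerical conventions: IoU of two zero-area boxes is defined as 0
(avoiding 0/0); the confidence filter is strict (>) while NMS is inclusive
(≥), following the stated wording of each rule; detection success is
strict (> 0.45); max-pooling ties route gradients to the first window
position; NMS confidence ties keep scan order; the 1024-gradation source
range normalises as value/1023; resize interpolation is bilinear; the one
box annotation printed as side lengths "(h, y)" in the source material is
read as the (w, h) used everywhere else. Tiled inference runs on the
resized image (consistent with the stated processing order). Boxes
straddling window edges are kept as decoded; edge truncation is a known
failure mode of the individual-detector pipeline and the ensemble is the
stated remedy.

## Grad-CAM

`gradcam_map()` implements the contribution map
$G_c = \mathrm{ReLU}\!\left(\sum_k \alpha^k_c A^k\right)$ with
$\alpha^k_c = \tfrac{1}{Z}\sum_{i,j} \partial y_c / \partial A^k_{ij}$,
gradients of non-target classes zeroed. For a multi-box detector the class
score $y_c$ is not defined by the original formulation; the package defines
it as the summed class-$c$ logit over boxes surviving the confidence
filter (falling back to the single most confident box), which makes the
map answer "what supported the boxes this pipeline actually reported".
The raw map stays at feature-map resolution; `gradcam_upsample()` is
bilinear and used for overlay rendering only.

## Known limitations

- The tiny detector is a machinery-scale model; no claim of clinical
  detection performance is made or testable here.
- Carpal and foot joints, erosion/JSN scoring and the final mTSS
  computation are out of scope (the upstream method defers them too).
- The phantom's two-timepoint "drift" is geometric jitter, not disease
  progression; longitudinal scoring is not modelled.
- DICOM input is not read directly (no DICOM reader is available to this
  package); rasters are exchanged as PNG (8-bit) or TIFF (16-bit, full
  1024-gradation fidelity).
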