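---
title: "Automated Ki-67 scoring: models, parameters and design notes"
author: "ki67score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated Ki-67 scoring: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67score)
```

## The problem

Ki-67 is a nuclear protein expressed in proliferating cells. In breast
cancer grading, the proliferation index is read from
immunohistochemically stained tissue: nuclei expressing Ki-67 stain brown
(DAB, *immunopositive*), resting nuclei stain blue (hematoxylin only,
*immunonegative*). The proliferation score is

$$\mathrm{APS}(\%) = \frac{\mathrm{TIP}}{\mathrm{TIP}+\mathrm{TIN}} \times 100,$$

where TIP and TIN are the immunopositive and immunonegative nucleus
counts, categorized against the clinical reference ranges: low (< 15 %),
average (16–30 %), high (> 31 %). Manual counting is slow and
observer-dependent; this package automates it in three stages: seed-point
detection, patch classification, and score aggregation.

## Stage 1: mixture-model seed detection

Pixel intensities are 3-vectors (RGB). Each of the three semantic classes
— immunopositive nucleus, immunonegative nucleus, background — is modeled
by a weighted mixture of full-covariance Gaussians,

$$p(x \mid c) = \sum_{j=1}^{m} w_{c,j}\, \mathcal{N}(x; \mu_{c,j}, \Sigma_{c,j}),$$

fitted by expectation–maximization. (The family is Gaussian throughout;
a per-channel Gamma variant could be slotted in behind the same density
interface, but the multivariate Gaussian is the form that matches the
energy function below.) MAP labeling assigns each pixel the class with
the largest posterior; with the optional Potts prior ($\beta > 0$) the
objective gains a pairwise term $\beta\,[K_p \neq K_q]$ over 4-neighbor
pairs and is optimized by iterated conditional modes (ICM) with
checkerboard sweeps, which is exact coordinate descent on the energy. The
Gaussian data term of the labeling energy is

$$U(I \mid K, \Theta) = \sum_Q \tfrac{1}{2}(I_Q-\mu_{K_Q})^\top
\Sigma_{K_Q}^{-1}(I_Q-\mu_{K_Q}) + \tfrac{1}{2}\ln\lvert\Sigma_{K_Q}\rvert.$$

Seed points are the rounded centroids of the 8-connected components of
each nucleus class, after discarding components below
`min_component_area`.

Numerical choices that matter:

* **EM initialization.** For generic fitting, k-means on a pixel
  subsample ($\le$ 100k pixels) with a fixed seed. For the detection
  pipeline, components are initialized at reference stain colors (DAB
  brown ≈ (150, 100, 60), hematoxylin blue ≈ (70, 80, 150), pale
  background ≈ (235, 230, 240)). A scarce class — a handful of brown
  nuclei in a low-proliferation field is 2–3 % of pixels — is otherwise
  easily lost to a k-means local optimum that splits the background
  instead. EM still adapts all means, covariances and weights to the
  image.
* **Degenerate classes.** On a field containing no nuclei of some class,
  that class's components collapse onto the background during EM. A
  nucleus class whose fitted mean ends up within `min_stain_separation`
  (default 30 RGB units; the brown–blue–background separations are
  ~120) of the background mean is declared absent, so a blank image
  yields zero detections and an undefined score rather than noise
  components.
* **Covariance floor.** `covariance_floor` (default 1 intensity²) is
  added to covariance diagonals each M-step. It keeps point-mass inputs
  well-defined and bounds the likelihood; the log-likelihood trace is
  non-decreasing up to this regularization, and the test suite asserts
  monotonicity at a relative tolerance of 1e-6.
* **Ties** in MAP labeling break toward the lowest class index
  (immunopositive < immunonegative < background), documented and
  deterministic.
* **$\beta$ defaults to 0** (pure maximum-likelihood labeling). The form
  of the smoothness prior is genuinely open in the source description;
  the Potts family is the simplest Gibbs prior consistent with a
  unary-plus-pairwise decomposition, and ICM from the unary labeling is
  the simplest optimizer whose fixed points are single-flip local minima.
  On high-contrast synthetic scenes smoothing is unnecessary; the test
  suite verifies the $\beta>0$ path against exhaustive enumeration on a
  toy image instead.
* **Fitting is per image** (a corpus-level fit is available by pooling
  pixels before `fit_gmm_em()`); labeling always uses every pixel even
  when fitting subsampled.

## Stage 2: the patch classifier

Each seed yields a 71 × 71 RGB patch centered on the centroid (71 is odd,
so the centroid is an exact center pixel; the half-pixel ambiguity of an
even size never arises). Near image borders the default policy reflects
the image content, which preserves patch counts without introducing
constant-color regions that would bias a color-driven classifier;
`constant` and `skip` policies are available.

The classifier is a convolutional network with a differentiable
decision-forest layer:

| stage | output |
|---|---|
| input | 71 × 71 × 3 |
| conv 90 @ 2×2 + ReLU | 70 × 70 |
| maxpool 2×2 | 35 × 35 |
| conv 180 @ 4×4 + ReLU | 32 × 32 |
| maxpool 2×2 | 16 × 16 |
| conv 360 @ 3×3 + ReLU | 14 × 14 |
| maxpool 2×2 | 7 × 7 |
| conv 720 @ 2×2 + ReLU | 6 × 6 |
| maxpool 2×2 | 3 × 3 |
| conv 1440 @ 2×2 + ReLU | 2 × 2 |
| decision layer (45 trees × depth 4) | 720 |
| FC 100 + ReLU + dropout 0.5 | 100 |
| FC 2 + softmax | 2 |

Convolutions are valid (no padding), stride 1 — the only reading
consistent with the printed arithmetic (71 → 70 under 2×2, 35 → 32 under
4×4). Pooling is non-overlapping with stride = window and floor division
on odd sides (7 → 3).

**The decision layer.** Each tree is a full binary tree of depth $d$.
Every decision node carries an affine functional $f_r$ of the flattened
final-convolution output; its routing decision is
$f_d(x) = \sigma(f_r(x))$, sending probability mass $f_d$ left and
$1-f_d$ right. The probability of reaching leaf $p$ is the product of
decisions along the path, so $\sum_p \mu_p(x) = 1$ per tree. A tree's
class prediction is $P_T[y \mid x] = \sum_p \pi_{py}\,\mu_p(x)$ and a
forest averages its trees.

Two readings of this layer are coherent, and the package implements
both. In the printed architecture the layer sits *between* conv-5 and
FC-1 with width 720, which only makes sense if its output is a feature
vector; the default **embedding mode** therefore concatenates all trees'
leaf-reach probabilities ($45 \times 2^4 = 720$) and feeds them to the FC
head. The **probability mode** (per-tree class posteriors, the
classifier reading) is exposed for standalone forest use, with leaf
distributions $\pi$ parameterized by a per-leaf softmax and learned by
the same SGD. Only the product $z \cdot 2^{\text{depth}} = 720$ is fixed
by the architecture; the factorization 45 × 16 is configurable. The
affine $f_r$ is the minimal differentiable choice for a "real-valued
function" and matches the standard neural-decision-forest construction.

**Training.** Mini-batch SGD with momentum on softmax cross-entropy (the
loss is otherwise unspecified in the source; cross-entropy is the
standard choice for two-class posteriors), with Caffe-style updates
$v \leftarrow mv - \eta(\nabla L + \lambda \theta)$,
$\theta \leftarrow \theta + v$. Reference defaults: learning rate 0.01,
momentum 0.85, weight decay 0.005, batch 128, 450,000 iterations,
evaluation every 5,000. Dropout (ratio 0.5) follows FC-1 only, is active
only during training, and uses inverted scaling so inference needs no
correction. ReLU follows each of the five convolutions and FC-1. Weights
use scaled-uniform fan-in initialization from a fixed seed; all
randomness (initialization, batch sampling, dropout) flows from one
`rng_seed`, so a run is reproducible bit-for-bit.

**Desk-scale profile.** The reference schedule is a multi-day GPU
workload. `desk_network_config()` keeps the exact topology and spatial
chain but narrows the maps (6/12/24/24/48, an 8-tree depth-3 forest,
FC 32), and `desk_train_config()` runs 300 iterations at batch 32. On
the synthetic task this reaches validation accuracy ≥ 0.95 in a few CPU
minutes; the full-width configuration remains expressible and the
architecture-conformance checks always run against it. The problem sizes
used by the automated checks — ~2,000 patches from 25 synthetic scenes,
300 iterations — were chosen as the smallest sizes at which the
classifier's behavior is unambiguous.

## Stage 3: scoring and evaluation

`score_image()` composes the stages: detect seeds → crop patches →
classify → count → `compute_aps()`. An image with no detections returns
an explicitly undefined score, never 0.

**Metric conventions.** Precision = TP/(TP+FP), recall = TP/(TP+FN),
F = harmonic mean of the *unrounded* precision and recall, rounded only
for display. The source method's printed formulas swap the FP/FN
denominators, but its own printed results (0.93/0.88 from the published
confusion matrix) are reproduced only by the standard definitions, which
are therefore the default; `convention = "as_printed"` exposes the
swapped variant for auditability. Undefined metrics (zero denominators)
are reported as `NA`, not 0.

**Category boundaries.** The reference ranges leave [15, 16) and
(30, 31] unassigned. The package closes them as
low < 15 ≤ average ≤ 30 < high: exhaustive, order-preserving, and
consistent with every published category placement. One published
category-error figure (0.01 for the average band) does not equal the
absolute difference of its own published manual and automated means
(|27.64 − 27.99| = 0.35); the package reproduces only the
internally consistent 0.06 and 0.00 anchors.

**Cross-validation** is stratified k-fold (default 5, each fold holding
20 % ± 1 patch of every class), with fold assignment continuing one
cycle across classes so fold totals are balanced. Grouping all patches
of a source image into one fold is available (`group_by_image = TRUE`)
as leakage control; it is off by default because it cannot satisfy the
exact 20 %-per-fold contract for unbalanced or single-image inputs, and
because on synthetic scenes with per-nucleus ground truth leakage is not
a concern.

## The synthetic-scene generator

The published image set (450 fields of 2048 × 1536 at 40×) is not
deposited, so the package generates IHC-like scenes with known ground
truth: rotated ellipses with semi-axes uniform in `nucleus_radius_range`
(default 8–14 px at the default 256² scale), per-nucleus Gaussian color
jitter (SD 8) around the class colors, additive pixel noise (SD 5)
clipped to 8 bits, on a pale background. Defaults were chosen once to
emulate the qualitative appearance of DAB/hematoxylin fields — strongly
separated class colors (brown–blue distance ≈ 122 RGB units) with
moderate within-class variation — and per-image APS targets spanning the
three clinical categories. At `overlap_fraction = 0`, bounding circles
are kept 2 px apart so rasterized masks never touch; larger values allow
proportional interpenetration.

What the generator does *not* model: chromatin texture, stain
deconvolution artifacts, out-of-focus blur, stromal structure,
touching/overlapping nuclei chains, scanner illumination gradients.
Passing the end-to-end checks therefore demonstrates that the
implementation is internally correct and that the pipeline recovers
known ground truth under controlled appearance variation — not that it
matches pathologist performance on clinical material. The coordinate
convention is 1-based (row, col) with row increasing downward, the
native convention of R arrays, and is used consistently in seed tables
and CSV output.

## Known limitations

* Merged nuclei are detected as one component (no watershed splitting);
  at `overlap_fraction > 0` the seed count undercounts the truth.
* The EM fitter assumes three color populations; heavy stain variation
  would require per-class component counts > 1
  (`components_per_class`).
* ICM reaches single-flip local minima of the Potts energy, not global
  optima.
* Training at the full reference width is supported but impractical on a
  CPU; all shipped checks train the desk profile.
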