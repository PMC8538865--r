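---
title: "Multi-resolution slot attention for explainable image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution slot attention for explainable image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`mrslots` implements an image classifier whose decision *is* an attention
map. A convolutional backbone produces feature grids $F_1, \dots, F_n$ at
$n$ spatial resolutions, level 1 the highest-resolution grid and level $n$
the deepest. The stride plan is fixed per backbone kind: the tiny backbone
halves the resolution per block (/2, /4, /8, /16 — its deepest grid at
64 px input is 4 × 4, mirroring the deep-grid-to-input ratio of the
full-scale 360 px design point), while the resnet50-style kind uses the
/4, /8, /16, /32 plan of its namesake. Each level carries its own
slot-attention module with $K$ slots, one per class.

## Slot attention per level

Tokens are the level's feature columns projected to a common dimension $D$
plus a learned positional grid (one grid per level; levels have different
spatial sizes, so sharing would be ill-defined). For slots $S \in
\mathbb{R}^{K \times D}$ and tokens $X \in \mathbb{R}^{P \times D}$, one
iteration computes

$$ \mathrm{logits}_{k,p} = \tfrac{1}{\sqrt{D}}\,
   \langle q(S_k),\, k(X_p) \rangle, $$

normalizes them with a softmax **across slots** — the competition that
suppresses attention won by other classes, so each position's slot weights
sum to 1 — renormalizes within each slot over tokens, and reads out the
attention-weighted mean of the value projections. All $K$ slots are then
refined jointly by a shared GRU whose input is $e \cdot U$ ($U$ the update,
$e = \pm 1$ the explanation sign) followed by a multi-layer perceptron.
After $T$ iterations (default 3) the final iteration's logits yield two
objects:

* the **competition weights** `attn` (softmax over slots; the normalization
  invariant tested throughout), and
* the **class-evidence maps** `maps` $= \sigma(\gamma\,\mathrm{logits} +
  \beta)$, nonnegative maps whose *free* total mass carries the
  classification signal.

The distinction matters: a softmax-normalized quantity has constant total
mass ($\sum_{k,p} A_{k,p} = P$), so it cannot serve as a saliency weight, a
class score, or an area penalty — all three need a mass that the model can
raise or lower. The sigmoid evidence map supplies that mass, in the spirit
of slot-based classifiers where the slot's attention total doubles as its
class confidence. $\gamma, \beta$ (per level, initialized to identity) let
the evidence sharpness decouple from the feature scale the competition
operates on; without them the area regularizer caps the achievable logit
margins.

## Fusion rule

Level $l$'s saliency is $W_l$, the mean of its evidence-map elements
(a size-normalized total: with the raw sum, a level's weight would scale
with its pixel count and the shallowest grid — 64 times larger than the
deepest — would dominate by construction; `saliency_mode = "sum"` is
available). The fused map at input resolution is the saliency-weighted
average of bilinearly upsampled level maps

$$ S_F = \sum_l \frac{W_l}{\sum_j W_j}\; \mathrm{up}(S_l), $$

a convex combination, so every fused pixel stays inside the min/max
envelope of the upsampled inputs, and the weights sum to 1 (uniform
fallback if all saliencies are zero).

## Classifier and loss

The class score is the total evidence mass of the slot at the **deepest**
level, signed by the explanation mode:
$\mathrm{logit}_k = e \sum_{h,w} M^{(n)}_{k,h,w}$. With $e = +1$ the model
is trained to place attention on evidence *for* the true class; with
$e = -1$ the class with the *least* attention wins, so training pushes
attention away from the true class and onto the others — the diagonal of an
attention confusion matrix is dark for a positive model and light for a
negative one.

Training minimizes

$$ L = L_{CE} + \lambda\, W, \qquad W = \sum_l W_l , $$

cross-entropy on the mass logits plus $\lambda$ times the total attention
area summed over all levels (per-level saliencies as above; regularizing
every level is what drives the shallow, uncertain levels toward zero weight
and lets the deep levels dominate the fusion). $\lambda$ (default 2)
controls how large the highlighted regions may grow.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `input_size` | 360 (desk preset 64) | square input side, bilinear resize |
| `n_levels` | 4 | pyramid levels; 1 = low-resolution pathway |
| `dim` (D) | 64 | token/slot dimension |
| `T` | 3 | slot iterations (shared parameters) |
| `e` | +1 | explanation sign |
| `lambda` | 2 | area-regularizer weight |
| `batch_size`, `lr` | 32, 1e-4 (desk 1e-3) | AdamW settings |
| `epochs` | 80 (desk 30) | training length |
| `threshold_frac` | 0.1 | overlay alpha cut at this fraction of the map max |

The desk preset (`desk_config()`) — 64 px inputs, the tiny 16/32/64/128
backbone, D = 32, 30 epochs, lr 1e-3, weight decay 1e-4, augmentation
per-method probability 0.15, area warm-up 18 epochs + 6-epoch ramp — is
what the test-suite and the reproduction script use; the full-scale
defaults remain available for larger studies.

# Numerical and design choices

**Slot initialization.** Slots start from learned per-class mean vectors
(Gaussian-initialized at construction); `init_slots()` can draw around them
with a learned log-std. Training and inference use the means, so inference
is deterministic. A single mean shared by all slots would make every slot
identical at inference — attention permanently uniform and prediction at
chance — which is why the means are per-slot.

**Residual refinement.** The post-GRU MLP is residual and the GRU update
gate's bias starts at +2 (gate ≈ 0.88). The refinement map is shared across
slots, and without these two choices it contracts the $K$ slot vectors onto
a single point within three iterations (we measured a ~10x loss of
between-slot spread per forward pass at initialization), erasing the class
identities the classifier depends on.

**Area-term warm-up.** The area penalty acts along the uniform-logit
direction, which softmax cross-entropy is invariant to — CE cannot oppose
it. Under an adaptive optimizer whose step size is scale-free, any
$\lambda > 0$ therefore drives an *undiscriminating* model into sigmoid
saturation (all evidence ≈ 0, vanishing gradients) within tens of steps.
Training holds $\lambda$ at zero for `lambda_warmup` epochs (default 10)
and ramps it over `lambda_ramp` (default 5): once the classes are
separated, class-specific evidence is defended by the cross-entropy and the
penalty prunes background attention instead of killing the model. The
final objective is unchanged. (A backbone with strong pretrained features
would not need this, since discrimination exists from the first step.)

**Bilinear convention.** All resampling (input resize, fusion upsampling,
mask resize, warps) maps output pixel centers by
`src = (dst + 0.5) * in/out - 0.5` with clamped borders: constants are
preserved exactly and a 1 × 1 map broadcasts.

**Ties and degenerate inputs.** All-zero saliencies fall back to uniform
fusion weights; an all-zero attention map renders a fully transparent
overlay with a warning; `T = 0` returns the initial slots and their
attention; `n_levels = 1` makes the fused map exactly the upsampled deepest
map. Class prediction uses `which.max`, i.e. the lowest index on exact
ties.

# The synthetic study

`synthetic_spec()` emulates the structure of single-plant seedling datasets:
one object per image whose *shape family* defines the class (thin-blade
cluster vs broad-petaled rosette vs four-armed cross vs ring of discs —
mimicking the narrow- vs broad-leaved distinction), growth-stage-like size
variation (default 25–60% of the image side), random orientation, a small
position jitter, and a stone-speckle background (bright blobs on soil, the
kind of background clutter attention is known to leak onto) plus Gaussian
pixel noise. Ground-truth masks come free, which is what makes localization
scoring exact: the *enrichment* of a map is its mass fraction inside the
mask divided by the mask's area fraction, with a uniform map scoring
exactly 1.

What the generator does **not** emulate: real leaf texture and venation,
illumination changes between acquisitions, occlusion and partial plants,
growth-stage label structure, or class imbalance (classes are balanced by
default). Passing tests on this generator therefore demonstrate that the
architecture, losses and evaluation machinery behave as specified — not
that the model reaches any particular accuracy on real field imagery.

**Study sizes.** The reproduction script and the acceptance tests train the
positive-explanation model at K = 4, 64 × 64, 200 train / 100 test images
per class for 30 epochs; the negative-explanation twin and the
λ ∈ {0, 2, 10} comparison use 100 train / 50 test per class at 15 and 12
epochs with a correspondingly shorter warm-up (6 + 3 epochs) — sizes chosen
so the full study runs on a single desk CPU, with the sign and λ checks
asserted on directions rather than magnitudes.

# Known limitations

* The tiny backbone's deepest grid at 64 px input is 4 × 4, so fused maps
  localize at 16-px granularity; finer localization comes only from
  shallower levels when their saliency survives the area penalty.
* The backbone is a plain conv stack; the `"resnet50"` kind reproduces
  stage widths and strides, not the residual topology, and no pretrained
  weights are shipped.
* Negative-explanation training inherits the sign through both the GRU
  input and the logit (`logit = e * mass`); with the sign on the GRU input
  alone the optimizer would simply absorb it and positive/negative models
  would not differ in their attention structure.
* Training is single-process CPU; wall-clock scales with
  `input_size^2 * dim`.
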