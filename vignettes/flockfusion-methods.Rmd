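---
title: "Methods: multimodal fusion regression for livestock traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal fusion regression for livestock traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flockfusion)
```

## The problem

Live weight and carcass composition (carcass weight, fat mass, lean
mass) drive nutrition, breeding and slaughter decisions in sheep
production, but the accurate instruments — scales and CT — are stressful
or impractical on farm. `flockfusion` models these four traits jointly
from a pair of photographs (dorsal and lateral view) plus two tabular
covariates a stockperson can supply in seconds: a body condition score
(BCS, the palpation-based 1–5 fatness scale) and a coarse size category
(small / medium / large). The package implements the full method stack —
data assembly with animal-level leakage control, three fusion
architectures, uncertainty-weighted multi-task training, agreement
statistics and Grad-CAM explanations — together with a synthetic flock
generator so that every claim the test suite makes is checkable on a
desk without animal data.

## The synthetic flock generator

The generator is first-class, tested code, not a fixture. It emulates a
commercial ewe flock with the following generative model, one
independent random stream per animal (derived from the seed and the
animal id, so flocks are reproducible and order-independent):

* **Live weight** `LW ~ N(mu0, sigma0)` truncated to `[48.0, 88.5]` kg by
  rejection (no boundary atoms). The parent parameters `(mu0, sigma0)`
  are solved numerically so that the *truncated* distribution has mean
  62.4 kg and SD 8.7 kg; without this correction the truncation would
  shift the mean by ≈0.9 kg and shrink the SD. `truncnorm_moments()`
  exposes the closed-form moments used in the solve.
* **Fat mass** `FM = exp(m + s·Z2)` with `m = log 5.5`, `s = 0.55`,
  truncated to `[0.88, 17.64]` kg, where `Z2` shares a latent Gaussian
  factor with the live-weight draw at correlation 0.6. Rejection is
  sequential — live weight first, then fat mass conditional on the
  accepted latent — so the live-weight marginal stays exactly the
  truncated normal above (a joint rejection would leak the fat-mass
  truncation into the live-weight moments).
* **Carcass weight** `CW = 0.44·LW + N(0, 0.5 kg)` (a typical
  dressing-out fraction), **bone mass** `= 0.18·CW`, and fat is capped at
  `min(FM, 0.55·CW)` so that **lean mass** `LM = CW − FM − bone` is
  positive for every possible draw. `FM + LM + bone = CW` therefore
  holds *exactly*, and the test suite asserts it to machine precision.
* **Covariates**: BCS is the within-flock rank-quantile of the fat ratio
  `FM/CW` mapped onto `1 + 4q`, rounded to the half-point 1–5 scale
  (ties broken by animal id); the size category comes from live-weight
  tertiles. The half-point granularity is a convention choice — the
  common field practice — not a calibrated quantity.

All constants other than the published population moments and trait
bounds (dressing fraction, bone fraction, fat cap, lognormal parameters,
latent correlation) are the package's own choices, picked once for
biological plausibility (positive lean mass everywhere, LW–FM
correlation ≈ 0.5) and deliberately not revisited.

### Rendering

Images are schematic: a two-lobed (thoracic + rump) ellipse silhouette
on a flat background, plus a pure-red reference bar standing in for the
field scale marker, plus additive Gaussian background and fleece-texture
noise. The body half-width in pixels is

```
b = intercept + lw_slope · LW + fm_slope · modifier(size) · FM
```

per view (defaults at 64 px: dorsal `3 + 0.25·LW + 0.08·mod·FM`,
lateral `4 + 0.16·LW + 0.16·mod·FM`, scaled linearly with image size).
Two properties are engineered and tested:

* **Decodability** — at zero noise, OLS of live weight on dorsal body
  pixel area reaches R² ≥ 0.95 over 200 animals; a model that cannot
  learn live weight from these images is broken, not data-starved.
* **Confounding that rewards fusion** — the fat-mass slope is modulated
  by the size category (×1.6 small, ×1.0 medium, ×0.4 large), so fat
  mass is *not* identifiable from pixels alone. This gives the
  image-only ablation a real handicap and the tabular branch a real
  contribution, which the ablation tests exploit directionally.

What the generator does **not** emulate: wool texture, breed-specific
conformation, perspective and lens distortion, lighting fields,
occlusion, background clutter. Passing tests therefore demonstrate the
*mechanics* of the pipeline (fusion, leakage control, loss behaviour,
explanation plausibility) — they say nothing about accuracy on real
photographs.

## Dataset assembly

Partitioning is by animal, never by image: `partition_animals()`
shuffles ids deterministically and applies `floor(0.70·n)` /
`ceil(0.15·n)` / remainder — the unique simple rounding rule that maps
156 animals onto 109/24/23. Cross-validation folds
(`assign_folds()`) use shuffle + round-robin so fold sizes differ by at
most one. The fixed augmentation suite materializes exactly five
variants per training image — original, horizontal flip, +8°, −8°,
+20 % brightness — mirroring the five-panel-per-view convention; a
stochastic per-epoch mode (flip p = 0.5, rotation U(−8°, 8°), brightness
U(0.8, 1.2)) is available for on-the-fly training. Rotation fills
exposed corners with the image's border colour. `verify_no_leakage()`
checks two invariants on any assembled dataset: no animal's images span
partitions, and no augmented image sits outside the training set;
`augment_training_images()` additionally refuses already-augmented
input, so double augmentation cannot happen by construction.

## Architectures

All families are size-configurable; the shipped `*_tiny` presets
(64 × 64 inputs) are what the tests train, and 224-px presets mirror
full-scale backbones without being exercised at desk scale. Named
activation conventions per family: ReLU (baseline), Swish (attention
fusion), GELU (token fusion).

* **`baseline_concat`** — a strided-conv backbone per view (shared
  weights), global average pooling, channel concatenation of the two
  view vectors with the tabular MLP output, then a two-layer head with 4
  outputs.
* **`attention_fusion`** — the same backbone with a CBAM block after
  *every* stage (the insertion point is a design choice; the reference
  description does not fix it). CBAM applies a channel gate (shared
  two-layer bottleneck over average- and max-pooled channel descriptors,
  sigmoid) then a spatial gate (convolution over channel-wise mean and
  max maps, sigmoid). Fusion is single-query scaled dot-product
  attention: the tabular encoding is projected to a query against the
  final feature map's spatial vectors; the attended context is
  concatenated with the tabular encoding before the head.
* **`token_fusion`** — patches of both views are flattened, linearly
  projected to `embed_dim`, given additive positional embeddings (shared
  across views), a per-view role embedding, and joined into one sequence
  with a single tabular token (the tabular MLP output projected to token
  width) prepended at position 0 with its own positional embedding. A
  pre-LayerNorm Transformer encoder (MHSA + GELU MLP, residual)
  processes the sequence; the tabular token's final state feeds a linear
  head. A `fusion = "concat"` variant of the same family — mean-pooled
  patch tokens concatenated with the tabular embedding — exists solely
  for the fusion ablation.

Whether the two views share backbone weights is configurable in spirit;
the implementation shares them, the simplest choice consistent with
swappable families. The joint single sequence (rather than per-view
encoders) is likewise the simplest mechanism by which self-attention can
capture cross-view geometry.

## Training

Targets are standardized with training-set moments (stored on the
model); the loss operates on the standardized scale and predictions are
de-standardized for reporting. The multi-task objective is the
homoscedastic-uncertainty form `Σ_t exp(−s_t)·MSE_t + s_t` with the four
log-variances `s_t` learnable and initialized at −0.5. Useful
identities, both tested: the loss reduces to the plain MSE sum at
`s = 0`, and the gradient in `s_t` vanishes exactly at
`s_t = log(MSE_t)`, where the per-task term equals `1 + log(MSE_t)`.
The mechanism is named in the source description but not given as a
formula; this standard form is the package's choice, with "similar
weights across targets" read as equal initialization of all `s_t`.

Optimizers: Adam, AdamW (decoupled decay; log-variances are never
decayed) and SGD with momentum. Schedules: step decay
(`base·gamma^floor(e/step)`), cosine (`base·(1+cos(pi·e/T))/2`, clamped
at the horizon) and warmup-cosine (linear 0→base over the warmup, then
cosine). Early stopping monitors the validation value of the uncertainty
loss with the current frozen `s`, restores the best-epoch weights, and
stops after `patience` non-improving epochs. With a fixed seed and
single-threaded execution two runs are bit-identical (tested); the
multi-run stability protocol trains replicates under init seeds derived
deterministically from the base seed — the natural reading of a
"same seed, different initialization" protocol, which is contradictory
if taken literally.

Grid search is exhaustive over a discrete space, scored by the mean
validation MAE across the four targets, ties broken first-seen,
non-finite (diverged) scores excluded. The ablation harness retrains
each variant under identical seed, splits and augmentation: backbone
swap, per-target single-task models, a zeroed tabular branch
(image-only), concatenation fusion, and no-augmentation/no-regularization.

## Evaluation and agreement statistics

R² is the coefficient of determination `1 − SSE/SST` (it may be
negative), not squared correlation, since predictions need not be
calibrated. Lin's CCC uses population (1/n) moments — the standard Lin
definition — while Bland–Altman uses the sample (n−1) SD for its
±1.96 SD limits; both conventions are stated because neither is fixed by
the problem. Bland–Altman additionally reports the slope of differences
against pair means as a proportional-bias diagnostic. Model comparisons
are two-sided paired t (via `stats::t.test`) and a Wilcoxon signed-rank
test implemented in the package: zeros dropped, average ranks for ties,
and an exact null for n ≤ 25 built by dynamic-programming convolution
over doubled ranks (average ranks are half-integers, so doubling makes
the support integral); beyond that, a normal approximation with tie
correction and continuity correction. The exact path is verified against
full 2^n sign-flip enumeration and, in the tie-free case, against
`stats::wilcox.test`; the base function is the oracle there, not the
implementation, because it has no exact tie-aware path.

## Grad-CAM for regression

For the convolutional families, the gradient of one regression output
with respect to a stage's post-activation feature map gives per-channel
weights (spatial means); the rectified weighted channel sum is
normalized by its maximum and bilinearly upsampled to the input
resolution. Max-normalization (rather than min–max) keeps an
identically-zero map zero instead of undefined — the zero map is a
meaningful answer ("this output ignores the image"). One heatmap per
view, default layer = final stage. The token-fusion family exposes no
convolutional maps and is deliberately out of scope for this operation.
The tested plausibility property is the literal, desk-scale analogue of
expert map review: on zero-noise renders, a trained tiny model's mean
heatmap intensity inside the body silhouette exceeds the background mean
on at least 90 % of animals.

## Numerical choices

* Regression heads are zero-initialized: an untrained model predicts the
  (standardized) target mean, and the token model's outputs are exactly
  zero before training — a convenient, tested fixed point.
* Pre-LayerNorm residual blocks; no LayerNorm before the head readout,
  so the token's residual stream can carry scale information to a linear
  head.
* The CBAM spatial convolution uses replicate (edge-clamped) padding,
  with the backward pass folding the pad ring back onto edge pixels:
  with zero padding a spatially constant map would get a non-constant
  gate at the borders, breaking an obvious symmetry.
* Convolutions run as im2col matrix products with cached index maps;
  backward accumulation uses `rowsum` over the same indices. All
  backward passes — attention, LayerNorm, CBAM (including its argmax
  paths), cross-modal attention, convolutions under both padding modes —
  are verified against central finite differences.
* Channel normalization defaults to the standard ImageNet statistics and
  is configurable per model.
* Images are H × W × 3 arrays in [0,1], row-major, origin top-left;
  manifests are UTF-8 CSV; model configs serialize to YAML; checkpoints
  are RDS with the config embedded.

## Problem sizes in the test suite

The suite runs entirely on synthetic data at sizes chosen to exercise
every mechanism while staying comfortably interactive: gradient checks
on 32-px micro models; the learning-sanity run trains the 64-px tiny
token-fusion preset (patch 8, 2 layers, 4 heads, width 64) on 120
animals for 30 epochs and requires held-out live-weight R² ≥ 0.8; the
ablation direction check uses 90 animals, 12 epochs and three seeds; the
explanation check trains the tiny CNN on 60 animals and scores 50 fresh
zero-noise renders; pipeline-count checks assemble the full 156-animal
dataset (109 training animals, 1090 augmented training images, 1184
images in total). The acceptance script samples 10,000 animals to pin
the generator's calibration.

## Known limitations

* The renderer is geometric, not photorealistic; conclusions about real
  imagery require real data.
* Tiny presets demonstrate mechanism, not capacity; the 224-px presets
  are constructible but training them in R at full scale is not the
  intended use.
* Pretrained backbone weights are not bundled; fine-tuning from
  published checkpoints is outside the package's scope.
* Single-threaded determinism is guaranteed; parallel BLAS may reorder
  floating-point reductions and relax bit-identity to statistical
  reproducibility.
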