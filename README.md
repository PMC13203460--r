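# flockfusion

Non-invasive estimation of sheep live weight and carcass composition from
photographs is an alternative to stressful manual weighing and to costly
CT scanning. `flockfusion` implements a hybrid multimodal regression
framework for this problem: paired dorsal (top-down) and lateral
(side-view) RGB images of a ewe are combined with two cheap tabular
covariates — the body condition score (BCS) and a size category — to
predict four continuous targets at once: live weight (LW), carcass weight
(CW), fat mass (FM) and lean mass (LM), all in kg.

The package is aimed at researchers in precision livestock farming and at
methodologists who want a fully inspectable, desk-scale implementation of
image–tabular fusion regression: every architectural component, the
multi-task loss, and the explainability pass are implemented in R with
hand-derived backward passes, and a calibrated synthetic flock generator
makes the whole pipeline testable without any animal data.

## What is implemented

**Three fusion families**, all sharing the contract
`(dorsal image, lateral image, bcs, size) -> (LW, CW, FM, LM)`:

* `baseline_concat` — per-view CNN features, globally pooled, concatenated
  with an MLP encoding of the tabular record, then a shared regression
  head (feature-level fusion).
* `attention_fusion` — a CNN backbone whose stages carry CBAM blocks
  (sequential channel and spatial attention), fused by single-query
  cross-modal attention in which the tabular encoding is the query and
  the spatial feature vectors are keys/values.
* `token_fusion` — a Vision-Transformer-style encoder: both views are cut
  into non-overlapping patches, linearly projected into tokens with
  positional and view-role embeddings, a single tabular token is
  prepended, and the tabular token's final state feeds the head.

**Multi-task training** uses the homoscedastic task-uncertainty loss

```
L = sum_t  exp(-s_t) * MSE_t + s_t
```

with one learnable log-variance `s_t` per target (initialized at −0.5),
so task weights are learned rather than hand-tuned. Training supports
Adam/AdamW/SGD-momentum, step/cosine/warmup-cosine schedules, early
stopping on validation loss, strict animal-level train/val/test
partitioning and 10-fold animal-level cross-validation, an augmentation
suite (flip, ±8° rotation, ±20 % brightness) applied to training images
only, leakage verification, a grid-search harness, and an ablation
harness (backbone swap, single-task, image-only, concatenation fusion,
no-regularization variants).

**Evaluation and agreement**: MAE, RMSE, R², MAPE, Lin's concordance
correlation coefficient, Bland–Altman bias and 95 % limits of agreement
(±1.96 SD), and paired t / exact Wilcoxon signed-rank comparisons of
model errors.

**Explainability**: Grad-CAM adapted to regression — gradients of a
chosen output with respect to a convolutional feature map give channel
weights; the rectified weighted channel sum, max-normalized and
bilinearly upsampled, highlights the body regions driving a prediction.

**Synthetic flock generator**: phenotypes are drawn from a truncated
normal live-weight law (moment-corrected so the *truncated* distribution
has mean 62.4 kg and SD 8.7 kg on bounds [48.0, 88.5] kg) with a
correlated lognormal fat mass truncated to [0.88, 17.64] kg;
`fat + lean + bone = carcass` holds exactly by construction. Rendered
images encode the targets in body-silhouette geometry, with a fat-mass
slope that depends on the size category so that fat mass is *not*
identifiable from pixels alone — multimodal fusion has something real to
learn.

## Worked example

```r
library(flockfusion)

flock <- sample_flock(60, seed = 1)
flock
#> <flock> 60 animals
#>   live weight: 48.2-82.1 kg (mean 62.4, SD 8.4)
#>   fat mass   : 2.32-16.64 kg

sp   <- partition_animals(flock$animal_id, seed = 1)   # 42 / 9 / 9 animals
rcfg <- render_config(background_noise_sd = 0.005, texture_noise_sd = 0.01)
ids  <- split(sp$animal_id, sp$partition)
train <- make_examples(flock, ids$train, rcfg, seed = 1)
val   <- make_examples(flock, ids$val,   rcfg, seed = 1)
test  <- make_examples(flock, ids$test,  rcfg, seed = 1)

cfg <- train_config(max_epochs = 20, batch_size = 16, base_lr = 1e-3, seed = 1,
                    scheduler = lr_scheduler("warmup_cosine", base_lr = 1e-3,
                                             warmup_epochs = 3, t_max = 17))
ft <- fit(ff_model(model_preset("vit_tiny"), seed = 1), train, val, cfg)
ft
#> <ff_fit> best epoch 15 / stopped 20 | best val loss 4.2869

evaluate_model(ft$model, test)
#>           target   mae  rmse    r2  mape
#> 1    live_weight 1.916 2.369 0.895  3.08
#> 2 carcass_weight 0.846 1.068 0.877  3.13
#> 3       fat_mass 0.757 1.054 0.858 10.79
#> 4      lean_mass 0.712 0.904 0.863  5.49
```

The tiny token-fusion model recovers live weight on nine held-out animals
with an MAE of 1.9 kg and R² of 0.90: the image geometry carries most of
the live-weight signal, while fat mass (R² 0.86, MAPE 10.8 %) needs the
tabular context because its visual imprint is confounded by the size
category. Agreement statistics on the same predictions:

```r
preds <- attr(evaluate_model(ft$model, test), "predictions")
truth <- attr(evaluate_model(ft$model, test), "truth")
lin_ccc(truth[, 1], preds[, 1])
#> 0.953
bland_altman(truth[, 1], preds[, 1])
#> bias +0.936 kg | LoA [-3.589, 5.461] | SD 2.309 | prop-bias slope 0.0941
```

A command-line wrapper covering the whole pipeline
(`simulate | split | train | evaluate | crossval | ablate | explain`)
ships as `inst/scripts/flockfusion`:

```sh
Rscript inst/scripts/flockfusion simulate --n 156 --seed 42 --out flock/
Rscript inst/scripts/flockfusion split --flock flock/flock.csv --out flock/
```

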