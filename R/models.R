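# Model configuration and the family-independent surface: every family
# accepts (dorsal image, lateral image, bcs, size category) and emits four
# regression targets, so families are swappable in the ablation harness.

FAMILIES <- c("baseline_concat", "attention_fusion", "token_fusion")

#' Configure a fusion model
#'
#' @param family `"baseline_concat"` (per-view CNN features concatenated
#'   with the tabular encoding), `"attention_fusion"` (CBAM-enhanced CNN
#'   features fused by cross-modal attention with the tabular encoding as
#'   query), or `"token_fusion"` (both views' patch tokens plus a tabular
#'   token through a Transformer encoder).
#' @param image_size input image side in pixels.
#' @param tabular_mlp_widths widths of the tabular-branch MLP.
#' @param activation `"relu"`, `"swish"` or `"gelu"` (defaults follow the
#'   family conventions: ReLU for the baseline, Swish for attention
#'   fusion, GELU for token fusion).
#' @param dropout dropout rate in \[0, 1).
#' @param conv_channels,conv_strides backbone stage widths/strides (conv
#'   families).
#' @param head_hidden hidden width of the regression head (conv families).
#' @param cbam_reduction CBAM channel bottleneck ratio (attention fusion).
#' @param d_att cross-modal attention dimension (attention fusion).
#' @param embed_dim,patch_size,n_heads,n_layers,mlp_ratio Transformer
#'   geometry (token fusion). `image_size` must be divisible by
#'   `patch_size`.
#' @param fusion `"token"` (tabular token in the sequence, its final state
#'   read out) or `"concat"` (patch tokens only, mean-pooled and
#'   concatenated with the tabular embedding) - the latter exists for the
#'   fusion ablation.
#' @return a `model_config` list.
#' @export
model_config <- function(family = c("token_fusion", "baseline_concat",
                                    "attention_fusion"),
                         image_size = 64L,
                         tabular_mlp_widths = c(16L, 32L, 16L),
                         activation = NULL,
                         dropout = 0.1,
                         conv_channels = c(8L, 16L, 32L, 32L),
                         conv_strides = c(2L, 2L, 2L, 1L),
                         head_hidden = 32L,
                         cbam_reduction = 2L,
                         d_att = 16L,
                         embed_dim = 64L, patch_size = 8L,
                         n_heads = 4L, n_layers = 2L, mlp_ratio = 2L,
                         fusion = c("token", "concat")) {
  family <- match.arg(family)
  fusion <- match.arg(fusion)
  activation <- activation %||% switch(family, baseline_concat = "relu",
                                       attention_fusion = "swish",
                                       token_fusion = "gelu")
  image_size <- check_count(image_size, "image_size", min = 16L)
  if (length(tabular_mlp_widths) == 0)
    ff_stop("tabular_mlp_widths must be non-empty",
            class = "ff_validation_error")
  check_scalar_num(dropout, "dropout", 0, 1 - 1e-9)
  if (family == "token_fusion") {
    if (image_size %% patch_size != 0)
      ff_stop("image_size must be divisible by patch_size",
              class = "ff_validation_error")
    if (embed_dim %% n_heads != 0)
      ff_stop("embed_dim must be divisible by n_heads",
              class = "ff_validation_error")
  }
  if (family %in% c("baseline_concat", "attention_fusion") &&
      length(conv_channels) != length(conv_strides))
    ff_stop("conv_channels and conv_strides must have equal length",
            class = "ff_validation_error")
  structure(list(family = family, image_size = image_size,
                 tabular_mlp_widths = as.integer(tabular_mlp_widths),
                 activation = activation, dropout = dropout,
                 conv_channels = as.integer(conv_channels),
                 conv_strides = as.integer(conv_strides),
                 head_hidden = as.integer(head_hidden),
                 cbam_reduction = as.integer(cbam_reduction),
                 d_att = as.integer(d_att),
                 embed_dim = as.integer(embed_dim),
                 patch_size = as.integer(patch_size),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 mlp_ratio = as.integer(mlp_ratio),
                 fusion = fusion),
            class = "model_config")
}

#' Named model presets
#'
#' `*_tiny` presets are the desk-scale configurations used throughout the
#' tests (64 x 64 inputs); the 224-pixel presets mirror the published
#' full-scale setups (ResNet18-, EfficientNet-B3- and ViT-B/16-class
#' backbones with tabular MLPs of 16/32/16, 32/64/32 and 64/128/64) and
#' are constructible but not exercised at desk scale.
#'
#' @param name preset name.
#' @export
model_preset <- function(name = c("cnn_tiny", "agff_tiny", "vit_tiny",
                                  "cnn_224", "agff_224", "vit_b16_224")) {
  name <- match.arg(name)
  switch(name,
    cnn_tiny = model_config("baseline_concat", image_size = 64L,
                            tabular_mlp_widths = c(16L, 32L, 16L),
                            dropout = 0.3),
    agff_tiny = model_config("attention_fusion", image_size = 64L,
                             tabular_mlp_widths = c(16L, 32L, 16L),
                             dropout = 0.4),
    vit_tiny = model_config("token_fusion", image_size = 64L,
                            patch_size = 8L, embed_dim = 64L, n_heads = 4L,
                            n_layers = 2L,
                            tabular_mlp_widths = c(16L, 32L, 16L),
                            dropout = 0.2),
    cnn_224 = model_config("baseline_concat", image_size = 224L,
                           conv_channels = c(64L, 128L, 256L, 512L),
                           conv_strides = c(4L, 2L, 2L, 2L),
                           tabular_mlp_widths = c(16L, 32L, 16L),
                           head_hidden = 256L, dropout = 0.3),
    agff_224 = model_config("attention_fusion", image_size = 224L,
                            conv_channels = c(40L, 96L, 192L, 384L),
                            conv_strides = c(4L, 2L, 2L, 2L),
                            tabular_mlp_widths = c(32L, 64L, 32L),
                            head_hidden = 256L, d_att = 64L, dropout = 0.4),
    vit_b16_224 = model_config("token_fusion", image_size = 224L,
                               patch_size = 16L, embed_dim = 768L,
                               n_heads = 12L, n_layers = 12L, mlp_ratio = 4L,
                               tabular_mlp_widths = c(64L, 128L, 64L),
                               dropout = 0.2))
}

#' Instantiate a model from a configuration
#'
#' @param config a [model_config()].
#' @param seed weight initialization seed.
#' @param image_only if `TRUE`, the tabular branch is zeroed (ablation).
#' @return an `ff_model`.
#' @export
ff_model <- function(config, seed = 42L, image_only = FALSE) {
  params <- withr::with_seed(as.integer(seed), {
    if (config$family == "token_fusion") init_token_model(config)
    else init_conv_model(config)
  })
  structure(list(config = config, params = params,
                 target_stats = list(mean = rep(0, 4), sd = rep(1, 4)),
                 channel_mean = c(0.485, 0.456, 0.406),
                 channel_sd = c(0.229, 0.224, 0.225),
                 image_only = image_only, init_seed = as.integer(seed)),
            class = c(config$family, "ff_model"))
}

#' @export
print.ff_model <- function(x, ...) {
  cat(sprintf("<ff_model> family %s | %d px | %s params%s\n",
              x$config$family, x$config$image_size,
              format(n_params(x), big.mark = ","),
              if (isTRUE(x$image_only)) " | image-only" else ""))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model an `ff_model`.
#' @export
n_params <- function(model) tree_n_params(model$params)

# ---- tabular encoding ------------------------------------------------------

tab_input_vec <- function(bcs, size_category) {
  if (!size_category %in% c("small", "medium", "large"))
    ff_stop("unknown size category: ", size_category,
            class = "ff_argument_error")
  check_scalar_num(bcs, "bcs", 1, 5)
  c(small = as.numeric(size_category == "small"),
    medium = as.numeric(size_category == "medium"),
    large = as.numeric(size_category == "large"),
    bcs = (bcs - 1) / 4)
}

#' Encode tabular covariates through the tabular-branch MLP
#'
#' The size category is one-hot encoded (3 values), concatenated with the
#' body condition score rescaled from \[1,5\] to \[0,1\], and passed through
#' an MLP of the given widths (hidden layers activated, final layer
#' linear).
#'
#' @param bcs body condition score in \[1,5\].
#' @param size_category `"small"`, `"medium"` or `"large"`.
#' @param widths MLP layer widths; output length is the last width.
#' @param activation hidden activation.
#' @param params optional list of linear layers (as produced by the model
#'   initializers); initialized from `seed` when `NULL`.
#' @param seed init seed used when `params` is `NULL`.
#' @return numeric feature vector.
#' @export
encode_tabular <- function(bcs, size_category, widths = c(16L, 32L, 16L),
                           activation = "relu", params = NULL, seed = 1L) {
  x <- matrix(tab_input_vec(bcs, size_category), 1, 4)
  if (is.null(params))
    params <- withr::with_seed(as.integer(seed), init_mlp(4L, widths))
  as.numeric(mlp_forward(x, params, activation)$out)
}

# ---- example preparation and the unified forward ---------------------------

normalize_image <- function(img, mean, sd) {
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - mean[ch]) / sd[ch]
  img
}

prepare_example <- function(model, dorsal, lateral, bcs, size_category,
                            targets = NULL) {
  cfg <- model$config
  if (dim(dorsal$image)[1] != cfg$image_size)
    ff_stop("input image size ", dim(dorsal$image)[1],
            " does not match model image_size ", cfg$image_size,
            class = "ff_argument_error")
  nd <- normalize_image(dorsal$image, model$channel_mean, model$channel_sd)
  nl <- normalize_image(lateral$image, model$channel_mean, model$channel_sd)
  ex <- list(tab = unname(tab_input_vec(bcs, size_category)),
             y = targets)
  if (cfg$family == "token_fusion") {
    ex$patches <- list(dorsal = extract_patches(nd, cfg$patch_size),
                       lateral = extract_patches(nl, cfg$patch_size))
  } else {
    ex$imgs <- list(dorsal = nd, lateral = nl)
  }
  ex
}

model_forward_any <- function(model, ex, train = FALSE) {
  if (model$config$family == "token_fusion")
    token_model_forward(model, ex, train)
  else conv_model_forward(model, ex, train)
}

model_backward_any <- function(model, cache, dpred, collect = NULL) {
  if (model$config$family == "token_fusion")
    token_model_backward(model, cache, dpred)
  else conv_model_backward(model, cache, dpred, collect)
}

#' Predict the four targets for one animal
#'
#' Runs the family-specific forward pass on a dorsal/lateral image pair
#' plus the tabular record and returns predictions on the kg scale
#' (de-standardized with the target statistics stored at training time).
#'
#' @param model an `ff_model`.
#' @param dorsal,lateral `image_sample`s of the two views.
#' @param bcs,size_category tabular covariates.
#' @return named numeric vector `(live_weight, carcass_weight, fat_mass,
#'   lean_mass)` in kg.
#' @export
forward_multitarget <- function(model, dorsal, lateral, bcs, size_category) {
  ex <- prepare_example(model, dorsal, lateral, bcs, size_category)
  out <- model_forward_any(model, ex, train = FALSE)
  pred <- out$pred * model$target_stats$sd + model$target_stats$mean
  if (any(!is.finite(pred)))
    ff_stop("non-finite prediction", class = "ff_numeric_error")
  stats::setNames(pred, c("live_weight", "carcass_weight", "fat_mass",
                          "lean_mass"))
}

# ---- config and checkpoint serialization ----------------------------------

#' Write / read a model configuration as YAML
#'
#' @param config a `model_config`.
#' @param path YAML file path.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(model_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    ff_stop("unknown config keys: ", paste(unknown, collapse = ", "),
            class = "ff_parse_error")
  do.call(model_config, vals)
}

#' Save / load a model checkpoint (weights plus embedded config)
#'
#' @param model an `ff_model`.
#' @param path checkpoint path (RDS container).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
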