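# Token-level fusion regressor: both views' patch tokens plus one tabular
# token pass through a Transformer encoder; the tabular token's final state
# feeds the four-target regression head. A "concat" fusion variant of the
# same family mean-pools the patch tokens and concatenates the tabular
# embedding before the head (used by the ablation harness).

# ---- patch extraction ------------------------------------------------------

#' Split an image into flattened non-overlapping patches
#'
#' @param img H x W x 3 array.
#' @param patch_size patch side in pixels; must divide the image side.
#' @return matrix with one row per patch (row-major over the patch grid),
#'   each row the flattened `patch_size^2 * 3` pixel values.
#' @export
extract_patches <- function(img, patch_size) {
  H <- dim(img)[1]
  if (dim(img)[2] != H)
    ff_stop("image must be square", class = "ff_argument_error")
  if (H %% patch_size != 0)
    ff_stop("image size ", H, " not divisible by patch size ", patch_size,
            class = "ff_argument_error")
  g <- H %/% patch_size
  out <- matrix(0, g * g, patch_size^2 * 3)
  k <- 0L
  for (i in seq_len(g)) {
    rows <- (i - 1) * patch_size + seq_len(patch_size)
    for (j in seq_len(g)) {
      k <- k + 1L
      cols <- (j - 1) * patch_size + seq_len(patch_size)
      out[k, ] <- img[rows, cols, ]
    }
  }
  out
}

#' Project an image into a positional- and view-embedded token sequence
#'
#' Patches are flattened, linearly projected to `embed_dim`, and given
#' additive positional embeddings plus a view-role embedding chosen by the
#' sample's view tag.
#'
#' @param sample an `image_sample`.
#' @param patch_size,embed_dim patch side and token dimension.
#' @param params optional parameter list (`patch` linear, `pos` P x D,
#'   `view` 2 x D); initialized from `seed` when `NULL`.
#' @param seed init seed used when `params` is `NULL`.
#' @return a `token_sequence`: list with `tokens` (P x D matrix) and
#'   `roles` (`"patch_dorsal"` or `"patch_lateral"` per token).
#' @export
patchify_and_tokenize <- function(sample, patch_size, embed_dim,
                                  params = NULL, seed = 1L) {
  patches <- extract_patches(sample$image, patch_size)
  P <- nrow(patches)
  if (is.null(params)) {
    params <- withr::with_seed(as.integer(seed), list(
      patch = init_linear(ncol(patches), embed_dim),
      pos = matrix(stats::rnorm(P * embed_dim, 0, 0.02), P, embed_dim),
      view = matrix(stats::rnorm(2 * embed_dim, 0, 0.02), 2, embed_dim)))
  }
  vi <- if (sample$view == "dorsal") 1L else 2L
  tokens <- linear_forward(patches, params$patch)$out + params$pos +
    matrix(params$view[vi, ], P, embed_dim, byrow = TRUE)
  structure(list(tokens = tokens,
                 roles = rep(paste0("patch_", sample$view), P)),
            class = "token_sequence")
}

# ---- encoder block forward/backward ---------------------------------------

token_block_forward <- function(x, bp, n_heads, act, drop = NULL) {
  ln1 <- layernorm_forward(x, bp$ln1_g, bp$ln1_b)
  att <- mhsa_forward(ln1$out, bp$attn, n_heads)
  att_o <- apply_mask(att$out, drop$attn %||% NULL)
  x2 <- x + att_o
  ln2 <- layernorm_forward(x2, bp$ln2_g, bp$ln2_b)
  h1 <- linear_forward(ln2$out, bp$mlp1)
  a1 <- act_forward(h1$out, act)
  h2 <- linear_forward(a1, bp$mlp2)
  m_o <- apply_mask(h2$out, drop$mlp %||% NULL)
  list(out = x2 + m_o, ln1 = ln1, att = att, x2 = x2, ln2 = ln2,
       h1 = h1, a1 = a1, h2 = h2, drop = drop)
}

token_block_backward <- function(dout, cache, bp, n_heads, act) {
  dx2 <- dout
  dm_o <- apply_mask(dout, cache$drop$mlp %||% NULL)
  bk2 <- linear_backward(dm_o, cache$h2, bp$mlp2)
  da1 <- bk2$dx * act_grad(cache$h1$out, act)
  bk1 <- linear_backward(da1, cache$h1, bp$mlp1)
  ln2b <- layernorm_backward(bk1$dx, cache$ln2, bp$ln2_g)
  dx2 <- dx2 + ln2b$dx
  datt <- apply_mask(dx2, cache$drop$attn %||% NULL)
  attb <- mhsa_backward(datt, cache$att, bp$attn, n_heads)
  ln1b <- layernorm_backward(attb$dx, cache$ln1, bp$ln1_g)
  dx <- dx2 + ln1b$dx
  list(dx = dx,
       grads = list(ln1_g = ln1b$dgamma, ln1_b = ln1b$dbeta,
                    attn = attb$grads,
                    ln2_g = ln2b$dgamma, ln2_b = ln2b$dbeta,
                    mlp1 = bk1$grads, mlp2 = bk2$grads))
}

token_encoder_forward <- function(blocks, x, n_heads, act, drops = NULL) {
  caches <- vector("list", length(blocks))
  for (l in seq_along(blocks)) {
    caches[[l]] <- token_block_forward(x, blocks[[l]], n_heads, act,
                                       drops[[l]] %||% NULL)
    x <- caches[[l]]$out
  }
  list(out = x, caches = caches)
}

token_encoder_backward <- function(dout, fwd, blocks, n_heads, act) {
  grads <- vector("list", length(blocks))
  dx <- dout
  for (l in rev(seq_along(blocks))) {
    bk <- token_block_backward(dx, fwd$caches[[l]], blocks[[l]], n_heads, act)
    grads[[l]] <- bk$grads
    dx <- bk$dx
  }
  list(dx = dx, grads = grads)
}

# ---- token model init ------------------------------------------------------

init_token_model <- function(cfg) {
  D <- cfg$embed_dim
  P <- (cfg$image_size %/% cfg$patch_size)^2
  pdim <- cfg$patch_size^2 * 3
  widths <- cfg$tabular_mlp_widths
  blocks <- lapply(seq_len(cfg$n_layers), function(l) {
    list(ln1_g = rep(1, D), ln1_b = numeric(D),
         attn = list(Wqkv = matrix(stats::rnorm(D * 3 * D, 0, 0.02), D, 3 * D),
                     bqkv = numeric(3 * D),
                     Wo = matrix(stats::rnorm(D * D, 0, 0.02), D, D),
                     bo = numeric(D)),
         ln2_g = rep(1, D), ln2_b = numeric(D),
         mlp1 = init_linear(D, cfg$mlp_ratio * D),
         mlp2 = init_linear(cfg$mlp_ratio * D, D))
  })
  head_in <- if (cfg$fusion == "token") D else 2 * D
  list(patch = init_linear(pdim, D),
       pos = matrix(stats::rnorm(P * D, 0, 0.02), P, D),
       pos_tab = matrix(stats::rnorm(D, 0, 0.02), 1, D),
       view = matrix(stats::rnorm(2 * D, 0, 0.02), 2, D),
       tab_mlp = init_mlp(4L, widths),
       tab_proj = init_linear(widths[length(widths)], D),
       blocks = blocks,
       head = list(W = matrix(0, head_in, 4), b = numeric(4)))
}

# ---- token model forward/backward (one prepared example) -------------------

token_model_forward <- function(model, ex, train = FALSE) {
  cfg <- model$config
  p <- model$params
  D <- cfg$embed_dim
  P <- nrow(p$pos)
  tab_in <- matrix(ex$tab, 1, 4)
  tabf <- mlp_forward(tab_in, p$tab_mlp, cfg$activation)
  tabp <- linear_forward(tabf$out, p$tab_proj)
  use_tab <- !isTRUE(model$image_only)

  emb_d <- linear_forward(ex$patches$dorsal, p$patch)
  emb_l <- linear_forward(ex$patches$lateral, p$patch)
  tok_d <- emb_d$out + p$pos + matrix(p$view[1, ], P, D, byrow = TRUE)
  tok_l <- emb_l$out + p$pos + matrix(p$view[2, ], P, D, byrow = TRUE)

  tab_tok <- if (use_tab) tabp$out + p$pos_tab else p$pos_tab
  x <- if (cfg$fusion == "token") rbind(tab_tok, tok_d, tok_l)
       else rbind(tok_d, tok_l)

  drops <- NULL
  if (train && cfg$dropout > 0) {
    drops <- lapply(seq_len(cfg$n_layers), function(l)
      list(attn = dropout_mask(dim(x), cfg$dropout),
           mlp = dropout_mask(dim(x), cfg$dropout)))
  }
  enc <- token_encoder_forward(p$blocks, x, cfg$n_heads, cfg$activation, drops)

  if (cfg$fusion == "token") {
    feat <- enc$out[1, , drop = FALSE]
  } else {
    pooled <- colMeans(enc$out)
    feat <- cbind(matrix(pooled, 1), if (use_tab) tabp$out else 0 * tabp$out)
  }
  head <- linear_forward(feat, p$head)
  list(pred = as.numeric(head$out),
       cache = list(tabf = tabf, tabp = tabp, emb_d = emb_d, emb_l = emb_l,
                    enc = enc, head = head, feat = feat, use_tab = use_tab,
                    S = nrow(x)))
}

token_model_backward <- function(model, cache, dpred) {
  cfg <- model$config
  p <- model$params
  D <- cfg$embed_dim
  P <- nrow(p$pos)
  hb <- linear_backward(matrix(dpred, 1, 4), cache$head, p$head)

  S <- cache$S
  denc <- matrix(0, S, D)
  dtabp_direct <- NULL
  if (cfg$fusion == "token") {
    denc[1, ] <- hb$dx
  } else {
    denc <- matrix(rep(hb$dx[1, 1:D] / S, each = S), S, D)
    dtabp_direct <- matrix(hb$dx[1, D + 1:D], 1, D)
  }
  encb <- token_encoder_backward(denc, cache$enc, p$blocks, cfg$n_heads,
                                 cfg$activation)
  dx <- encb$dx

  if (cfg$fusion == "token") {
    dtab_tok <- dx[1, , drop = FALSE]
    dtok_d <- dx[1 + seq_len(P), , drop = FALSE]
    dtok_l <- dx[1 + P + seq_len(P), , drop = FALSE]
  } else {
    dtab_tok <- matrix(0, 1, D)
    dtok_d <- dx[seq_len(P), , drop = FALSE]
    dtok_l <- dx[P + seq_len(P), , drop = FALSE]
  }

  g_pos <- dtok_d + dtok_l
  g_view <- rbind(colSums(dtok_d), colSums(dtok_l))
  bk_d <- linear_backward(dtok_d, cache$emb_d, p$patch)
  bk_l <- linear_backward(dtok_l, cache$emb_l, p$patch)
  g_patch <- tree_add(bk_d$grads, bk_l$grads)

  g_pos_tab <- dtab_tok
  dtabp_out <- if (cache$use_tab) dtab_tok else matrix(0, 1, D)
  if (!is.null(dtabp_direct) && cache$use_tab)
    dtabp_out <- dtabp_out + dtabp_direct
  tpb <- linear_backward(dtabp_out, cache$tabp, p$tab_proj)
  tmb <- mlp_backward(tpb$dx, cache$tabf, p$tab_mlp, cfg$activation)

  list(grads = list(patch = g_patch, pos = g_pos, pos_tab = g_pos_tab,
                    view = g_view, tab_mlp = tmb$grads,
                    tab_proj = tpb$grads, blocks = encb$grads,
                    head = hb$grads))
}
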