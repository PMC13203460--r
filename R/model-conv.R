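# Convolutional fusion families: a feature-concatenation baseline and an
# attention-guided fusion network (CBAM-enhanced backbone + cross-modal
# attention where the tabular encoding queries the visual feature map).
# Convolutions run as im2col matrix products with cached index maps.

.conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  iout <- rep(seq_len(Ho), times = Wo)
  jout <- rep(seq_len(Wo), each = Ho)
  base_row <- (iout - 1L) * stride
  base_col <- (jout - 1L) * stride
  di <- rep(seq_len(k), times = k * C)
  dj <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  idx <- outer(base_row, di, "+") + Hp * outer(base_col, dj - 1L, "+") +
    matrix((cc - 1L) * Hp * Wp, length(iout), length(di), byrow = TRUE)
  group <- as.vector(idx)
  info <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
               ug = sort(unique(group)), group = group)
  .conv_idx_cache[[key]] <- info
  info
}

conv_forward <- function(x, p, stride = 1L, pad = 1L,
                         pad_mode = c("zero", "replicate")) {
  pad_mode <- match.arg(pad_mode)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  k <- as.integer(sqrt(nrow(p$W) / C))
  ci <- conv_indices(H, W, C, k, stride, pad)
  padded <- array(0, c(ci$Hp, ci$Wp, C))
  padded[pad + seq_len(H), pad + seq_len(W), ] <- x
  if (pad_mode == "replicate" && pad > 0) {
    for (i in seq_len(pad)) {
      padded[i, , ] <- padded[pad + 1, , ]
      padded[pad + H + i, , ] <- padded[pad + H, , ]
    }
    for (j in seq_len(pad)) {
      padded[, j, ] <- padded[, pad + 1, ]
      padded[, pad + W + j, ] <- padded[, pad + W, ]
    }
  }
  col <- padded[ci$idx]
  dim(col) <- dim(ci$idx)
  out_mat <- sweep(col %*% p$W, 2, p$b, "+")
  list(out = array(out_mat, c(ci$Ho, ci$Wo, ncol(p$W))),
       col = col, ci = ci, in_dim = d, stride = stride, pad = pad,
       pad_mode = pad_mode)
}

conv_backward <- function(dout, cache, p) {
  ci <- cache$ci
  dout_mat <- matrix(dout, ci$Ho * ci$Wo, ncol(p$W))
  dW <- crossprod(cache$col, dout_mat)
  db <- colSums(dout_mat)
  dcol <- dout_mat %*% t(p$W)
  dpad <- numeric(ci$Hp * ci$Wp * cache$in_dim[3])
  acc <- rowsum(as.vector(dcol), ci$group)
  dpad[ci$ug] <- acc[, 1]
  dim(dpad) <- c(ci$Hp, ci$Wp, cache$in_dim[3])
  p0 <- cache$pad
  H <- cache$in_dim[1]; W <- cache$in_dim[2]
  if (identical(cache$pad_mode, "replicate") && p0 > 0) {
    # fold the replicated ring back onto the edge pixels it mirrors
    # (columns first, then rows: the reverse of the forward fill order)
    for (j in seq_len(p0)) {
      dpad[, p0 + 1, ] <- dpad[, p0 + 1, ] + dpad[, j, ]
      dpad[, p0 + W, ] <- dpad[, p0 + W, ] + dpad[, p0 + W + j, ]
    }
    for (i in seq_len(p0)) {
      dpad[p0 + 1, , ] <- dpad[p0 + 1, , ] + dpad[i, , ]
      dpad[p0 + H, , ] <- dpad[p0 + H, , ] + dpad[p0 + H + i, , ]
    }
  }
  dx <- dpad[p0 + seq_len(H), p0 + seq_len(W), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

init_conv <- function(C_in, C_out, k = 3L) {
  fan <- k * k * C_in
  list(W = matrix(stats::rnorm(fan * C_out, 0, sqrt(2 / fan)), fan, C_out),
       b = numeric(C_out))
}

# ---- CBAM: sequential channel then spatial attention -----------------------

init_cbam <- function(C, reduction = 2L, spatial_k = 5L) {
  Cr <- max(1L, C %/% reduction)
  list(ch1 = init_linear(C, Cr), ch2 = init_linear(Cr, C),
       sp = init_conv(2L, 1L, spatial_k))
}

cbam_forward_full <- function(x, p) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, HW, C)
  avg_c <- matrix(colMeans(xm), 1, C)
  max_i <- vapply(seq_len(C), function(j) which.max(xm[, j]), integer(1))
  max_c <- matrix(xm[cbind(max_i, seq_len(C))], 1, C)
  f_avg <- mlp_forward(avg_c, list(p$ch1, p$ch2), "relu")
  f_max <- mlp_forward(max_c, list(p$ch1, p$ch2), "relu")
  zc <- f_avg$out + f_max$out
  gate_c <- sigmoid(zc)
  x1m <- sweep(xm, 2, as.numeric(gate_c), "*")
  x1 <- array(x1m, d)

  sp_avg <- rowMeans(x1m)
  sp_max_i <- max.col(x1m, ties.method = "first")
  sp_max <- x1m[cbind(seq_len(HW), sp_max_i)]
  stack <- array(c(sp_avg, sp_max), c(d[1], d[2], 2))
  k <- as.integer(sqrt(nrow(p$sp$W) / 2))
  # replicate padding keeps the spatial gate constant on constant maps
  spc <- conv_forward(stack, p$sp, stride = 1L, pad = (k - 1L) %/% 2L,
                      pad_mode = "replicate")
  gate_s <- sigmoid(spc$out[, , 1])
  out <- x1 * as.vector(gate_s)
  list(out = out, xm = xm, x1m = x1m, d = d, gate_c = gate_c,
       gate_s = gate_s, f_avg = f_avg, f_max = f_max,
       max_i = max_i, sp_max_i = sp_max_i, spc = spc)
}

cbam_backward_full <- function(dout, cache, p) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]
  dout_m <- matrix(dout, HW, C)
  gs <- as.vector(cache$gate_s)
  dx1m <- dout_m * gs
  dgate_s <- rowSums(dout_m * cache$x1m)
  dzs <- dgate_s * gs * (1 - gs)
  spb <- conv_backward(array(dzs, c(d[1], d[2], 1)), cache$spc, p$sp)
  dstack <- spb$dx
  dsp_avg <- as.vector(dstack[, , 1])
  dsp_max <- as.vector(dstack[, , 2])
  dx1m <- dx1m + matrix(dsp_avg / C, HW, C)
  dx1m[cbind(seq_len(HW), cache$sp_max_i)] <-
    dx1m[cbind(seq_len(HW), cache$sp_max_i)] + dsp_max

  gc <- as.numeric(cache$gate_c)
  dxm <- sweep(dx1m, 2, gc, "*")
  dgate_c <- colSums(dx1m * cache$xm)
  dzc <- matrix(dgate_c * gc * (1 - gc), 1, C)
  bk_avg <- mlp_backward(dzc, cache$f_avg, list(p$ch1, p$ch2), "relu")
  bk_max <- mlp_backward(dzc, cache$f_max, list(p$ch1, p$ch2), "relu")
  dxm <- dxm + matrix(as.numeric(bk_avg$dx) / HW, HW, C, byrow = TRUE)
  dxm[cbind(cache$max_i, seq_len(C))] <-
    dxm[cbind(cache$max_i, seq_len(C))] + as.numeric(bk_max$dx)
  g_ch <- tree_add(bk_avg$grads, bk_max$grads)
  list(dx = array(dxm, d),
       grads = list(ch1 = g_ch[[1]], ch2 = g_ch[[2]], sp = spb$grads))
}

#' Apply a CBAM (channel then spatial attention) block to a feature map
#'
#' Channel attention gates each channel through a shared two-layer
#' bottleneck over average- and max-pooled channel descriptors; spatial
#' attention then gates each location through a convolution over the
#' channel-wise average and max maps. Both gates are sigmoids, so the
#' output never exceeds the input in absolute value and shapes are
#' preserved.
#'
#' @param fmap H x W x C feature map.
#' @param params optional CBAM parameters (`ch1`, `ch2` linear layers and
#'   `sp` convolution); initialized from `seed` when `NULL`.
#' @param reduction channel bottleneck reduction ratio.
#' @param spatial_k spatial attention kernel size (odd).
#' @param seed init seed used when `params` is `NULL`.
#' @return feature map of the same shape, with the gates as attributes
#'   `gate_channel` and `gate_spatial`.
#' @export
cbam_attend <- function(fmap, params = NULL, reduction = 2L, spatial_k = 5L,
                        seed = 1L) {
  if (length(dim(fmap)) != 3)
    ff_stop("fmap must be H x W x C", class = "ff_argument_error")
  if (is.null(params))
    params <- withr::with_seed(as.integer(seed),
                               init_cbam(dim(fmap)[3], reduction, spatial_k))
  fw <- cbam_forward_full(fmap, params)
  structure(fw$out, gate_channel = as.numeric(fw$gate_c),
            gate_spatial = fw$gate_s)
}

# ---- cross-modal attention fusion -----------------------------------------

init_cmf <- function(tab_dim, vis_dim, d_att) {
  list(Wq = matrix(stats::rnorm(tab_dim * d_att, 0, sqrt(1 / tab_dim)),
                   tab_dim, d_att),
       Wk = matrix(stats::rnorm(vis_dim * d_att, 0, sqrt(1 / vis_dim)),
                   vis_dim, d_att),
       Wv = matrix(stats::rnorm(vis_dim * d_att, 0, sqrt(1 / vis_dim)),
                   vis_dim, d_att))
}

cmf_forward <- function(tab, tokens, p) {
  q <- tab %*% p$Wq
  K <- tokens %*% p$Wk
  V <- tokens %*% p$Wv
  s <- (q %*% t(K)) / sqrt(ncol(q))
  w <- softmax_rows(s)
  ctx <- w %*% V
  list(fused = cbind(ctx, tab), w = w, q = q, K = K, V = V,
       tab = tab, tokens = tokens)
}

cmf_backward <- function(dfused, cache, p) {
  d_att <- ncol(cache$q)
  dctx <- dfused[, seq_len(d_att), drop = FALSE]
  dtab <- dfused[, d_att + seq_len(ncol(cache$tab)), drop = FALSE]
  dw <- dctx %*% t(cache$V)
  dV <- crossprod(cache$w, dctx)
  ds <- softmax_rows_backward(dw, cache$w) / sqrt(d_att)
  dq <- ds %*% cache$K
  dK <- crossprod(ds, cache$q)
  dtab <- dtab + dq %*% t(p$Wq)
  dtokens <- dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dtab = dtab, dtokens = dtokens,
       grads = list(Wq = crossprod(cache$tab, dq),
                    Wk = crossprod(cache$tokens, dK),
                    Wv = crossprod(cache$tokens, dV)))
}

#' Fuse a tabular feature vector with visual tokens by cross-modal attention
#'
#' Single-query scaled dot-product attention: the tabular vector supplies
#' the query, the visual tokens supply keys and values. The attention
#' weights are non-negative and sum to one; the output concatenates the
#' attention-weighted value combination with the tabular vector.
#'
#' @param tab_vec tabular feature vector.
#' @param visual_tokens matrix with one visual token per row.
#' @param params optional projections `Wq`, `Wk`, `Wv`; initialized from
#'   `seed` when `NULL` with `d_att` columns.
#' @param d_att attention dimension used when initializing.
#' @param seed init seed used when `params` is `NULL`.
#' @return list with `fused` (numeric vector) and `weights` (one weight
#'   per token).
#' @export
cross_modal_fuse <- function(tab_vec, visual_tokens, params = NULL,
                             d_att = 16L, seed = 1L) {
  if (is.null(dim(visual_tokens)))
    visual_tokens <- matrix(visual_tokens, nrow = 1)
  if (nrow(visual_tokens) == 0)
    ff_stop("visual token set must be non-empty", class = "ff_argument_error")
  if (is.null(params))
    params <- withr::with_seed(as.integer(seed),
                               init_cmf(length(tab_vec), ncol(visual_tokens),
                                        d_att))
  fw <- cmf_forward(matrix(tab_vec, 1), visual_tokens, params)
  list(fused = as.numeric(fw$fused), weights = as.numeric(fw$w))
}

# ---- conv model families ---------------------------------------------------

init_conv_model <- function(cfg) {
  ch <- cfg$conv_channels
  stages <- vector("list", length(ch))
  C_in <- 3L
  for (s in seq_along(ch)) {
    stages[[s]] <- list(conv = init_conv(C_in, ch[s]))
    if (cfg$family == "attention_fusion")
      stages[[s]]$cbam <- init_cbam(ch[s], cfg$cbam_reduction, 5L)
    C_in <- ch[s]
  }
  C_last <- ch[length(ch)]
  widths <- cfg$tabular_mlp_widths
  tab_out <- widths[length(widths)]
  p <- list(stages = stages, tab_mlp = init_mlp(4L, widths))
  if (cfg$family == "baseline_concat") {
    head_in <- 2L * C_last + tab_out
  } else {
    p$cmf <- init_cmf(tab_out, C_last, cfg$d_att)
    head_in <- cfg$d_att + tab_out
  }
  p$head1 <- init_linear(head_in, cfg$head_hidden)
  p$head2 <- list(W = matrix(0, cfg$head_hidden, 4), b = numeric(4))
  p
}

conv_backbone_forward <- function(img, p, cfg) {
  x <- img
  caches <- vector("list", length(p$stages))
  for (s in seq_along(p$stages)) {
    cf <- conv_forward(x, p$stages[[s]]$conv, stride = cfg$conv_strides[s],
                       pad = 1L)
    a <- act_forward(cf$out, cfg$activation)
    st <- list(conv = cf, act_in = cf$out, act_out = a)
    if (!is.null(p$stages[[s]]$cbam)) {
      st$cbam <- cbam_forward_full(a, p$stages[[s]]$cbam)
      x <- st$cbam$out
    } else x <- a
    st$out <- x
    caches[[s]] <- st
  }
  list(out = x, caches = caches)
}

# dtop is the gradient at the backbone output; optionally collects the
# gradient flowing into stage `collect` (its post-activation feature map)
conv_backbone_backward <- function(dtop, fwd, p, cfg, collect = NULL) {
  grads <- vector("list", length(p$stages))
  dx <- dtop
  collected <- NULL
  for (s in rev(seq_along(p$stages))) {
    st <- fwd$caches[[s]]
    g_cbam <- NULL
    if (!is.null(st$cbam)) {
      cb <- cbam_backward_full(dx, st$cbam, p$stages[[s]]$cbam)
      g_cbam <- cb$grads
      dx <- cb$dx
    }
    if (!is.null(collect) && collect == s) collected <- dx
    dx <- dx * act_grad(st$act_in, cfg$activation)
    cv <- conv_backward(dx, st$conv, p$stages[[s]]$conv)
    dx <- cv$dx
    # grads must mirror the parameter tree order exactly (conv, then cbam)
    grads[[s]] <- if (is.null(g_cbam)) list(conv = cv$grads)
                  else list(conv = cv$grads, cbam = g_cbam)
  }
  list(dx = dx, grads = grads, collected = collected)
}

conv_model_forward <- function(model, ex, train = FALSE) {
  cfg <- model$config
  p <- model$params
  tab_in <- matrix(if (isTRUE(model$image_only)) 0 * ex$tab else ex$tab, 1, 4)
  tabf <- mlp_forward(tab_in, p$tab_mlp, cfg$activation)
  bb_d <- conv_backbone_forward(ex$imgs$dorsal, p, cfg)
  bb_l <- conv_backbone_forward(ex$imgs$lateral, p, cfg)
  dmap <- bb_d$out; lmap <- bb_l$out
  dd <- dim(dmap); HW <- dd[1] * dd[2]; C <- dd[3]

  if (cfg$family == "baseline_concat") {
    feat <- cbind(matrix(colMeans(matrix(dmap, HW, C)), 1),
                  matrix(colMeans(matrix(lmap, HW, C)), 1),
                  tabf$out)
    cmf <- NULL
  } else {
    tokens <- rbind(matrix(dmap, HW, C), matrix(lmap, HW, C))
    cmf <- cmf_forward(tabf$out, tokens, p$cmf)
    feat <- cmf$fused
  }
  h1 <- linear_forward(feat, p$head1)
  a1 <- act_forward(h1$out, cfg$activation)
  mask <- if (train && cfg$dropout > 0) dropout_mask(dim(a1), cfg$dropout)
          else NULL
  a1d <- apply_mask(a1, mask)
  h2 <- linear_forward(a1d, p$head2)
  list(pred = as.numeric(h2$out),
       cache = list(tabf = tabf, bb_d = bb_d, bb_l = bb_l, cmf = cmf,
                    h1 = h1, a1 = a1, mask = mask, h2 = h2,
                    HW = HW, C = C, map_dim = dd))
}

conv_model_backward <- function(model, cache, dpred, collect = NULL) {
  cfg <- model$config
  p <- model$params
  hb2 <- linear_backward(matrix(dpred, 1, 4), cache$h2, p$head2)
  da1 <- apply_mask(hb2$dx, cache$mask) * act_grad(cache$h1$out,
                                                   cfg$activation)
  hb1 <- linear_backward(da1, cache$h1, p$head1)
  dfeat <- hb1$dx
  HW <- cache$HW; C <- cache$C

  g_cmf <- NULL
  if (cfg$family == "baseline_concat") {
    dgap_d <- dfeat[1, seq_len(C)]
    dgap_l <- dfeat[1, C + seq_len(C)]
    dtab_out <- dfeat[, 2 * C + seq_len(ncol(cache$tabf$out)), drop = FALSE]
    dmap_d <- array(matrix(dgap_d / HW, HW, C, byrow = TRUE), cache$map_dim)
    dmap_l <- array(matrix(dgap_l / HW, HW, C, byrow = TRUE), cache$map_dim)
  } else {
    cb <- cmf_backward(dfeat, cache$cmf, p$cmf)
    g_cmf <- cb$grads
    dtab_out <- cb$dtab
    dtok <- cb$dtokens
    dmap_d <- array(dtok[seq_len(HW), ], cache$map_dim)
    dmap_l <- array(dtok[HW + seq_len(HW), ], cache$map_dim)
  }
  bb_d <- conv_backbone_backward(dmap_d, cache$bb_d, p, cfg, collect)
  bb_l <- conv_backbone_backward(dmap_l, cache$bb_l, p, cfg, collect)
  g_stages <- tree_add(bb_d$grads, bb_l$grads)
  tmb <- mlp_backward(dtab_out, cache$tabf, p$tab_mlp, cfg$activation)

  grads <- list(stages = g_stages, tab_mlp = tmb$grads)
  if (!is.null(g_cmf)) grads$cmf <- g_cmf
  grads$head1 <- hb1$grads
  grads$head2 <- hb2$grads
  list(grads = grads,
       collected = list(dorsal = bb_d$collected, lateral = bb_l$collected))
}
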