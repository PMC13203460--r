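# Minimal neural-network layer library with hand-derived backward passes.
# Parameters live in nested named lists of matrices/vectors; gradients use
# the same structure, so optimizer updates can run on the flattened tree.

# ---- activations ----------------------------------------------------------

act_forward <- function(x, act) {
  switch(act,
    relu = pmax(x, 0),
    gelu = x * stats::pnorm(x),
    swish = x * stats::plogis(x),
    linear = x,
    ff_stop("unknown activation: ", act, class = "ff_argument_error"))
}

act_grad <- function(x, act) {
  switch(act,
    relu = (x > 0) * 1,
    gelu = stats::pnorm(x) + x * stats::dnorm(x),
    swish = {
      s <- stats::plogis(x)
      s + x * s * (1 - s)
    },
    linear = array(1, dim(x) %||% length(x)),
    ff_stop("unknown activation: ", act, class = "ff_argument_error"))
}

sigmoid <- function(x) stats::plogis(x)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# dP -> dZ through a row-wise softmax with output P
softmax_rows_backward <- function(dP, P) {
  (dP - rowSums(dP * P)) * P
}

# ---- parameter initialization --------------------------------------------

init_linear <- function(n_in, n_out, scale = NULL) {
  scale <- scale %||% sqrt(2 / (n_in + n_out))
  list(W = matrix(stats::rnorm(n_in * n_out, 0, scale), n_in, n_out),
       b = numeric(n_out))
}

init_mlp <- function(n_in, widths, scale = NULL) {
  dims <- c(n_in, widths)
  lapply(seq_along(widths), function(i)
    init_linear(dims[i], dims[i + 1], scale))
}

# ---- dense layers ---------------------------------------------------------

linear_forward <- function(x, p) {
  list(out = sweep(x %*% p$W, 2, p$b, "+"), x = x)
}

linear_backward <- function(dout, cache, p) {
  list(dx = dout %*% t(p$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

mlp_forward <- function(x, layers, act) {
  caches <- vector("list", length(layers))
  h <- x
  for (i in seq_along(layers)) {
    lin <- linear_forward(h, layers[[i]])
    pre <- lin$out
    h <- if (i < length(layers)) act_forward(pre, act) else pre
    caches[[i]] <- list(x = lin$x, pre = pre)
  }
  list(out = h, caches = caches)
}

mlp_backward <- function(dout, fwd, layers, act) {
  grads <- vector("list", length(layers))
  dh <- dout
  for (i in rev(seq_along(layers))) {
    if (i < length(layers)) dh <- dh * act_grad(fwd$caches[[i]]$pre, act)
    bk <- linear_backward(dh, fwd$caches[[i]], layers[[i]])
    grads[[i]] <- bk$grads
    dh <- bk$dx
  }
  list(dx = dh, grads = grads)
}

# hidden layers activated, last layer linear, activation applied to output
# of every layer (used by the tabular encoder where the final embedding is
# itself activated): controlled by `act_last`
mlp_forward_act <- function(x, layers, act, act_last = FALSE) {
  caches <- vector("list", length(layers))
  h <- x
  for (i in seq_along(layers)) {
    lin <- linear_forward(h, layers[[i]])
    pre <- lin$out
    h <- if (i < length(layers) || act_last) act_forward(pre, act) else pre
    caches[[i]] <- list(x = lin$x, pre = pre)
  }
  list(out = h, caches = caches)
}

mlp_backward_act <- function(dout, fwd, layers, act, act_last = FALSE) {
  grads <- vector("list", length(layers))
  dh <- dout
  for (i in rev(seq_along(layers))) {
    if (i < length(layers) || act_last)
      dh <- dh * act_grad(fwd$caches[[i]]$pre, act)
    bk <- linear_backward(dh, fwd$caches[[i]], layers[[i]])
    grads[[i]] <- bk$grads
    dh <- bk$dx
  }
  list(dx = dh, grads = grads)
}

# ---- layer norm (over the last dimension of an S x D matrix) --------------

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, inv = inv)
}

layernorm_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- multi-head self-attention (one sequence) ------------------------------

mhsa_forward <- function(x, p, n_heads) {
  D <- ncol(x)
  dh <- D %/% n_heads
  qkv <- sweep(x %*% p$Wqkv, 2, p$bqkv, "+")
  Q <- qkv[, 1:D, drop = FALSE]
  K <- qkv[, D + 1:D, drop = FALSE]
  V <- qkv[, 2 * D + 1:D, drop = FALSE]
  O <- matrix(0, nrow(x), D)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1) * dh + seq_len(dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
    A[[h]] <- softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- sweep(O %*% p$Wo, 2, p$bo, "+")
  list(out = out, x = x, Q = Q, K = K, V = V, A = A, O = O)
}

mhsa_backward <- function(dout, cache, p, n_heads) {
  D <- ncol(cache$x)
  dh <- D %/% n_heads
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- dK <- dV <- matrix(0, nrow(cache$x), D)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1) * dh + seq_len(dh)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- crossprod(Ah, dOh)
    dS <- softmax_rows_backward(dA, Ah) / sqrt(dh)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  dqkv <- cbind(dQ, dK, dV)
  list(dx = dqkv %*% t(p$Wqkv),
       grads = list(Wqkv = crossprod(cache$x, dqkv), bqkv = colSums(dqkv),
                    Wo = dWo, bo = dbo))
}

# ---- dropout ---------------------------------------------------------------

dropout_mask <- function(dim, rate) {
  if (rate <= 0) return(NULL)
  array(stats::rbinom(prod(dim), 1, 1 - rate) / (1 - rate), dim)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# ---- parameter-tree helpers and Adam --------------------------------------

tree_zeros_like <- function(tree) {
  if (is.list(tree)) lapply(tree, tree_zeros_like) else tree * 0
}

tree_add <- function(a, b) {
  if (is.list(a)) mapply(tree_add, a, b, SIMPLIFY = FALSE) else a + b
}

tree_n_params <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_n_params, numeric(1)))
  else length(tree)
}

adam_init <- function(params) {
  n <- length(unlist(params, use.names = FALSE))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

# decoupled weight decay (AdamW); `decay_mask` marks coordinates that decay
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      decay_mask = NULL) {
  th <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  step <- lr * mhat / (sqrt(vhat) + eps)
  if (weight_decay > 0) {
    wd <- if (is.null(decay_mask)) 1 else decay_mask
    step <- step + lr * weight_decay * th * wd
  }
  list(params = utils::relist(th - step, params), state = state)
}

sgd_momentum_step <- function(params, grads, state, lr, weight_decay = 0,
                              momentum = 0.9) {
  th <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  if (weight_decay > 0) g <- g + weight_decay * th
  state$m <- momentum * state$m + g
  state$t <- state$t + 1L
  list(params = utils::relist(th - lr * state$m, params), state = state)
}
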