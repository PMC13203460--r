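# Shared fixtures, generated in code at test time.

zero_noise_cfg <- function(image_size = 64L) {
  render_config(image_size = image_size,
                background_noise_sd = 0, texture_noise_sd = 0)
}

# small cached flocks so several test files can share one sampling call
.fixture_env <- new.env(parent = emptyenv())

cached_flock <- function(n, seed) {
  key <- paste0("flock_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- sample_flock(n, seed = seed)
  .fixture_env[[key]]
}

# a micro token-fusion config for fast mechanism tests
micro_token_cfg <- function(n_layers = 1L) {
  model_config("token_fusion", image_size = 32L, patch_size = 8L,
               embed_dim = 16L, n_heads = 2L, n_layers = n_layers,
               tabular_mlp_widths = c(8L, 8L), dropout = 0)
}

micro_examples <- function(flock, ids, seed = 1L) {
  make_examples(flock, ids, zero_noise_cfg(32L), seed = seed)
}

# finite-difference gradient check used by the backprop tests
max_rel_grad_err <- function(model, ex, n_coords = 40L, eps = 1e-5,
                             seed = 99L) {
  set.seed(seed)
  wvec <- stats::rnorm(4)
  fwd <- flockfusion:::model_forward_any(model, ex, train = FALSE)
  bk <- flockfusion:::model_backward_any(model, fwd$cache, wvec)
  ga <- unlist(bk$grads, use.names = FALSE)
  th <- unlist(model$params, use.names = FALSE)
  idx <- sample(length(th), min(n_coords, length(th)))
  gn <- vapply(idx, function(i) {
    m1 <- model
    t1 <- th; t1[i] <- t1[i] + eps
    m1$params <- utils::relist(t1, model$params)
    f1 <- sum(flockfusion:::model_forward_any(m1, ex)$pred * wvec)
    t2 <- th; t2[i] <- t2[i] - eps
    m1$params <- utils::relist(t2, model$params)
    f2 <- sum(flockfusion:::model_forward_any(m1, ex)$pred * wvec)
    (f1 - f2) / (2 * eps)
  }, numeric(1))
  max(abs(gn - ga[idx]) / pmax(1e-6, abs(gn) + abs(ga[idx])))
}
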