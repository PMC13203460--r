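# Model components: tabular encoder, CBAM, cross-modal attention,
# patchify, forward contract and parameter accounting.

test_that("tabular encoder output length and determinism follow the widths", {
  v <- encode_tabular(3.5, "medium", widths = c(16L, 32L, 16L))
  expect_length(v, 16L)
  expect_identical(v, encode_tabular(3.5, "medium", widths = c(16L, 32L, 16L)))
  expect_error(encode_tabular(3, "huge"), class = "ff_argument_error")
  expect_error(encode_tabular(7, "small"), class = "ff_argument_error")

  # identity-initialized single linear layer returns the raw encoding
  id_params <- list(list(W = diag(4), b = numeric(4)))
  out <- encode_tabular(1, "small", widths = 4L, params = id_params)
  expect_equal(out, c(1, 0, 0, 0))  # one-hot small, bcs scaled to 0
  out2 <- encode_tabular(5, "large", widths = 4L, params = id_params)
  expect_equal(out2, c(0, 0, 1, 1))
})

test_that("CBAM preserves shape, shrinks magnitudes and has an identity limit", {
  set.seed(21)
  fmap <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  out <- cbam_attend(fmap, seed = 2)
  expect_equal(dim(out), dim(fmap))
  expect_true(all(abs(out) <= abs(fmap) + 1e-12))
  gates_c <- attr(out, "gate_channel")
  expect_true(all(gates_c > 0 & gates_c < 1))

  # bias-saturated gates -> output equals input
  params <- withr::with_seed(2, flockfusion:::init_cbam(4L, 2L, 5L))
  params$ch2$b <- rep(50, 4)
  params$sp$b <- 50
  expect_equal(cbam_attend(fmap, params), fmap, ignore_attr = TRUE,
               tolerance = 1e-12)

  # spatially constant input -> constant spatial gate
  const <- array(rep(c(1, 2, 3), each = 25), c(5, 5, 3))
  out2 <- cbam_attend(const, seed = 3)
  gs <- attr(out2, "gate_spatial")
  expect_lt(diff(range(gs)), 1e-12)
})

test_that("cross-modal attention weights form a softmax over visual tokens", {
  # singleton token takes all the attention
  one <- cross_modal_fuse(c(1, 2), matrix(rnorm(3), 1, 3), d_att = 4)
  expect_equal(one$weights, 1)

  # identical tokens share attention uniformly
  tok <- matrix(rep(c(0.3, -1, 2), 5), 5, 3, byrow = TRUE)
  same <- cross_modal_fuse(c(1, 2), tok, d_att = 4)
  expect_equal(same$weights, rep(0.2, 5))

  # hand-sized oracle: identity projections, 2 tokens in 2 dimensions
  p <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2))
  tab <- c(1, 0.5)
  toks <- rbind(c(2, 0), c(0, 2))
  res <- cross_modal_fuse(tab, toks, params = p)
  s <- c(tab %*% t(toks)) / sqrt(2)
  w_hand <- exp(s) / sum(exp(s))
  expect_equal(res$weights, w_hand, tolerance = 1e-12)
  expect_equal(res$fused, c(w_hand %*% toks, tab), tolerance = 1e-12)

  expect_error(cross_modal_fuse(c(1, 2), matrix(numeric(0), 0, 3)),
               class = "ff_argument_error")
})

test_that("patchify produces the expected token grid", {
  img224 <- array(0.5, c(224, 224, 3))
  ts <- patchify_and_tokenize(image_sample("a", "dorsal", "original", img224),
                              patch_size = 16, embed_dim = 8)
  expect_equal(nrow(ts$tokens), 196L)
  expect_equal(unique(ts$roles), "patch_dorsal")

  img64 <- array(0.5, c(64, 64, 3))
  ts2 <- patchify_and_tokenize(image_sample("a", "lateral", "original", img64),
                               patch_size = 8, embed_dim = 8)
  expect_equal(nrow(ts2$tokens), 64L)
  expect_equal(unique(ts2$roles), "patch_lateral")

  ts3 <- patchify_and_tokenize(image_sample("a", "dorsal", "original", img64),
                               patch_size = 64, embed_dim = 8)
  expect_equal(nrow(ts3$tokens), 1L)

  expect_error(extract_patches(img64, 7), class = "ff_argument_error")
})

test_that("all families share the forward contract and are deterministic", {
  fl <- cached_flock(400, seed = 5)
  cfg <- zero_noise_cfg()
  d <- render_animal(fl[1, ], "dorsal", cfg)
  l <- render_animal(fl[1, ], "lateral", cfg)
  for (preset in c("cnn_tiny", "agff_tiny", "vit_tiny")) {
    m <- ff_model(model_preset(preset), seed = 31)
    p1 <- forward_multitarget(m, d, l, fl$bcs[1], fl$size_category[1])
    p2 <- forward_multitarget(m, d, l, fl$bcs[1], fl$size_category[1])
    expect_length(p1, 4L)
    expect_true(all(is.finite(p1)))
    expect_identical(p1, p2)
    expect_named(p1, c("live_weight", "carcass_weight", "fat_mass",
                       "lean_mass"))
  }
  # zero-initialized head -> all four outputs zero before training
  mt <- ff_model(model_preset("vit_tiny"), seed = 31)
  expect_equal(unname(forward_multitarget(mt, d, l, 3, "medium")),
               rep(0, 4))
})

test_that("tiny preset parameter counts match the closed-form expectation", {
  cfg <- model_preset("vit_tiny")
  m <- ff_model(cfg)
  D <- cfg$embed_dim; P <- (cfg$image_size / cfg$patch_size)^2
  pdim <- cfg$patch_size^2 * 3
  w <- cfg$tabular_mlp_widths
  mlp_n <- function(dims) sum((dims[-length(dims)] + 1) * dims[-1])
  block_n <- 2 * D + (D * 3 * D + 3 * D) + (D * D + D) + 2 * D +
    mlp_n(c(D, cfg$mlp_ratio * D, D))
  expected <- (pdim * D + D) + P * D + D + 2 * D +
    mlp_n(c(4, w)) + (w[length(w)] * D + D) +
    cfg$n_layers * block_n + (D * 4 + 4)
  expect_equal(n_params(m), expected)

  cfg2 <- model_preset("cnn_tiny")
  m2 <- ff_model(cfg2)
  ch <- cfg2$conv_channels
  conv_n <- sum((9 * c(3, ch[-length(ch)]) + 1) * ch)
  C <- ch[length(ch)]
  head_in <- 2 * C + 16
  expected2 <- conv_n + mlp_n(c(4, cfg2$tabular_mlp_widths)) +
    (head_in + 1) * cfg2$head_hidden + (cfg2$head_hidden + 1) * 4
  expect_equal(n_params(m2), expected2)
})

test_that("configs serialize to YAML and reject unknown keys", {
  cfg <- model_preset("vit_tiny")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_equal(back, cfg)
  y <- yaml::read_yaml(path)
  y$bogus_key <- 1
  yaml::write_yaml(y, path)
  expect_error(read_model_config(path), class = "ff_parse_error")
})

test_that("invalid model configurations are rejected", {
  expect_error(model_config("token_fusion", image_size = 60, patch_size = 8),
               class = "ff_validation_error")
  expect_error(model_config("token_fusion", embed_dim = 30, n_heads = 4),
               class = "ff_validation_error")
  expect_error(model_config("baseline_concat", dropout = 1),
               class = "ff_argument_error")
  expect_error(model_config("baseline_concat",
                            tabular_mlp_widths = integer(0)),
               class = "ff_validation_error")
})
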