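# Loss, schedulers, fit mechanics, stability report, CV, ablation plumbing
# and grid search.

test_that("uncertainty-weighted loss matches its closed form", {
  expect_equal(uncertainty_weighted_loss(rep(0, 4), rep(0, 4)), 0)
  expect_equal(uncertainty_weighted_loss(rep(1, 4), rep(-0.5, 4)),
               4 * (exp(0.5) - 0.5), tolerance = 1e-12)
  # reduces to the plain sum of MSEs when all log-variances are zero
  mse <- c(0.3, 1.2, 0.7, 2.5)
  expect_equal(uncertainty_weighted_loss(mse, rep(0, 4)), sum(mse))
  expect_error(uncertainty_weighted_loss(c(-1, 0, 0, 0), rep(0, 4)),
               class = "ff_argument_error")
  expect_error(uncertainty_weighted_loss(c(NA, 0, 0, 0), rep(0, 4)),
               class = "ff_numeric_error")
})

test_that("the loss gradient in s vanishes exactly at s = log(mse)", {
  mse <- c(0.4, 1.7, 0.9, 3.1)
  s_opt <- log(mse)
  eps <- 1e-6
  for (t in 1:4) {
    up <- dn <- s_opt
    up[t] <- up[t] + eps; dn[t] <- dn[t] - eps
    g <- (uncertainty_weighted_loss(mse, up) -
            uncertainty_weighted_loss(mse, dn)) / (2 * eps)
    expect_lt(abs(g), 1e-6)
    # and the per-task term at the optimum equals 1 + log(mse_t)
    expect_equal(exp(-s_opt[t]) * mse[t] + s_opt[t], 1 + log(mse[t]))
  }
  # analytic gradient used by the trainer agrees with finite differences
  s <- c(-0.5, 0.2, 0, 1)
  g_ana <- flockfusion:::uw_loss_grad_s(mse, s)
  g_num <- vapply(1:4, function(t) {
    up <- dn <- s; up[t] <- up[t] + eps; dn[t] <- dn[t] - eps
    (uncertainty_weighted_loss(mse, up) -
       uncertainty_weighted_loss(mse, dn)) / (2 * eps)
  }, numeric(1))
  expect_equal(g_ana, g_num, tolerance = 1e-6)
})

test_that("learning-rate schedules follow their closed forms", {
  st <- lr_scheduler("step_decay", base_lr = 1e-3, step_size = 20,
                     gamma = 0.5)
  expect_equal(scheduled_lr(st, 45), 2.5e-4)
  expect_equal(scheduled_lr(st, 0), 1e-3)

  co <- lr_scheduler("cosine", base_lr = 1e-3, t_max = 50)
  expect_equal(scheduled_lr(co, 0), 1e-3)
  expect_equal(scheduled_lr(co, 25), 5e-4)
  expect_equal(scheduled_lr(co, 200), scheduled_lr(co, 50))  # clamped

  wc <- lr_scheduler("warmup_cosine", base_lr = 1e-3, warmup_epochs = 5,
                     t_max = 95)
  expect_equal(scheduled_lr(wc, 5), 1e-3)  # ramp endpoint
  expect_equal(scheduled_lr(wc, 0), 0)
  expect_equal(scheduled_lr(wc, 2), 1e-3 * 2 / 5)
  expect_equal(scheduled_lr(wc, 5 + 95), 0, tolerance = 1e-18)
})

test_that("fit rejects empty or leaking datasets", {
  fl <- cached_flock(10, seed = 30)
  ex <- micro_examples(fl, fl$animal_id)
  m <- ff_model(micro_token_cfg(), seed = 1)
  expect_error(fit(m, list(), ex[1:2], train_config(max_epochs = 1)),
               class = "ff_argument_error")
  expect_error(fit(m, ex[1:4], ex[4:5], train_config(max_epochs = 1)),
               class = "ff_validation_error")
})

test_that("training is reproducible and early stopping follows patience", {
  fl <- cached_flock(10, seed = 30)
  ex <- micro_examples(fl, fl$animal_id)
  cfg <- train_config(max_epochs = 4, batch_size = 4, seed = 11,
                      base_lr = 1e-3,
                      scheduler = lr_scheduler("cosine", base_lr = 1e-3,
                                               t_max = 4))
  f1 <- fit(ff_model(micro_token_cfg(), seed = 2), ex[1:7], ex[8:10], cfg)
  f2 <- fit(ff_model(micro_token_cfg(), seed = 2), ex[1:7], ex[8:10], cfg)
  expect_identical(f1$history, f2$history)
  # the restored checkpoint has the lowest validation loss of the run
  expect_equal(f1$history$val_loss[f1$best_epoch],
               min(f1$history$val_loss))

  # a deliberately diverging run stops exactly patience epochs after best
  div_cfg <- train_config(max_epochs = 30, batch_size = 4, seed = 11,
                          base_lr = 30, patience = 2,
                          scheduler = lr_scheduler("step_decay",
                                                   base_lr = 30,
                                                   step_size = 100))
  fd <- fit(ff_model(micro_token_cfg(), seed = 2), ex[1:7], ex[8:10],
            div_cfg)
  expect_equal(fd$stopped_epoch, fd$best_epoch + 2L)
  expect_lt(fd$stopped_epoch, 30L)
})

test_that("stability report reproduces hand arithmetic", {
  # constant curves: gap is the printed difference, SDs are zero
  h <- data.frame(train_mae = rep(1.52, 12), val_mae = rep(1.95, 12))
  rep1 <- stability_report(h, window = 10)
  expect_equal(rep1$gap, 0.43, tolerance = 1e-12)
  expect_equal(rep1$train_sd, 0)
  expect_equal(rep1$val_sd, 0)

  # identical curves: zero gap
  h2 <- data.frame(train_mae = 1:12 / 10, val_mae = 1:12 / 10)
  expect_equal(stability_report(h2, 10)$gap, 0)

  # hand-built 10-epoch fixture
  tr <- c(2.0, 1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1)
  va <- tr + 0.5
  h3 <- data.frame(train_mae = tr, val_mae = va)
  rep3 <- stability_report(h3, 10)
  expect_equal(rep3$train_mean, mean(tr))
  expect_equal(rep3$train_sd, sd(tr))
  expect_equal(rep3$val_mean, mean(va))
  expect_equal(rep3$gap, 0.5, tolerance = 1e-12)

  expect_error(stability_report(h3[1:5, ], 10), class = "ff_argument_error")
})

test_that("cross-validation folds are disjoint, exhaustive and order-invariant", {
  fl <- cached_flock(10, seed = 30)
  mcfg <- micro_token_cfg()
  tcfg <- train_config(max_epochs = 2, batch_size = 4, seed = 3)
  cv <- run_cross_validation(fl, mcfg, tcfg, k = 2,
                             render_cfg = zero_noise_cfg(32L), seed = 3)
  expect_length(cv$folds, 2L)
  expect_true(all(is.finite(cv$aggregate$mae_mean)))
  fm <- cv$fold_manifest
  expect_setequal(fm$animal_id, fl$animal_id)
  expect_equal(anyDuplicated(fm$animal_id), 0L)

  # shuffling the roster does not change the results (fixed seed)
  fl_shuffled <- fl[rev(seq_len(nrow(fl))), ]
  cv2 <- run_cross_validation(fl_shuffled, mcfg, tcfg, k = 2,
                              render_cfg = zero_noise_cfg(32L), seed = 3)
  expect_equal(cv2$aggregate, cv$aggregate, tolerance = 1e-10)
})

test_that("metric aggregation across folds matches hand arithmetic", {
  vals <- list(c(mae = 2.0, r2 = 0.90), c(mae = 2.4, r2 = 0.84))
  m <- sapply(vals, `[[`, "mae")
  expect_equal(mean(m), 2.2)
  expect_equal(sd(m), sqrt(sum((m - 2.2)^2) / 1))
})

test_that("the ablation harness builds the requested variants", {
  mcfg <- model_preset("vit_tiny")
  tcfg <- train_config(max_epochs = 5, seed = 1)
  su <- flockfusion:::ablation_setup("image_only", mcfg, tcfg)
  expect_true(su$image_only)
  su2 <- flockfusion:::ablation_setup("concat_fusion", mcfg, tcfg)
  expect_equal(su2$model_cfg$fusion, "concat")
  su3 <- flockfusion:::ablation_setup("no_aug_no_reg", mcfg, tcfg)
  expect_equal(su3$model_cfg$dropout, 0)
  expect_equal(su3$train_cfg$weight_decay, 0)
  su4 <- flockfusion:::ablation_setup("backbone_swap", mcfg, tcfg)
  expect_equal(su4$model_cfg$family, "baseline_concat")
  expect_error(flockfusion:::ablation_setup("bogus", mcfg, tcfg),
               class = "ff_argument_error")

  # empty variant list -> table with only the full-model rows
  fl <- cached_flock(12, seed = 31)
  tab <- run_ablation(fl, micro_token_cfg(),
                      train_config(max_epochs = 2, batch_size = 4, seed = 3),
                      variants = character(0),
                      render_cfg = zero_noise_cfg(32L), seed = 3)
  expect_equal(unique(tab$variant), "full")
  expect_equal(nrow(tab), 4L)
})

test_that("grid search matches brute-force enumeration and breaks ties first-seen", {
  space <- list(base_lr = c(1e-3, 1e-2), batch_size = c(8, 16))
  stub <- function(row) {
    # precomputed stub losses keyed by the configuration
    key <- paste(row$base_lr, row$batch_size)
    c("0.001 8" = 2.0, "0.01 8" = 1.4, "0.001 16" = 3.0,
      "0.01 16" = 1.9)[[key]]
  }
  gs <- grid_search(space, eval_fn = stub)
  grid <- expand.grid(space)
  brute <- which.min(apply(grid, 1, function(r)
    stub(list(base_lr = r[1], batch_size = r[2]))))
  expect_equal(gs$best_index, unname(brute))
  expect_equal(gs$best$base_lr, 1e-2)
  expect_equal(gs$best$batch_size, 8)

  # ties broken by first-seen order
  gs_tie <- grid_search(list(a = c(1, 2, 3)), eval_fn = function(row) 7)
  expect_equal(gs_tie$best_index, 1L)

  # a diverging (non-finite) candidate never wins
  gs_div <- grid_search(list(a = c(1, 2)),
                        eval_fn = function(row)
                          if (row$a == 1) Inf else 5)
  expect_equal(gs_div$best$a, 2)

  # space of size one returns that configuration
  gs1 <- grid_search(list(a = 5), eval_fn = function(row) 1)
  expect_equal(gs1$best$a, 5)
  expect_error(grid_search(list()), class = "ff_argument_error")
})

test_that("grid search over real training picks a finite-score winner", {
  fl <- cached_flock(10, seed = 30)
  ex <- micro_examples(fl, fl$animal_id)
  gs <- grid_search(list(base_lr = c(1e-3, 50)),
                    model_cfg = micro_token_cfg(),
                    train_cfg = train_config(max_epochs = 2, batch_size = 4,
                                             seed = 5),
                    train = ex[1:7], val = ex[8:10])
  expect_true(is.finite(gs$scores$score[gs$best_index]))
  expect_equal(gs$best$base_lr, 1e-3)
})

test_that("repeated runs vary only by derived initialization seeds", {
  fl <- cached_flock(10, seed = 30)
  ex <- micro_examples(fl, fl$animal_id)
  rr <- run_repeated_training(micro_token_cfg(),
                              train_config(max_epochs = 2, batch_size = 4,
                                           seed = 9),
                              ex[1:7], ex[8:10], n_runs = 3)
  expect_equal(nrow(rr), 3L)
  expect_equal(length(unique(rr$init_seed)), 3L)
  expect_true(all(is.finite(attr(rr, "mae_sd"))))
})
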