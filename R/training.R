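# Multi-task training: homoscedastic task-uncertainty loss, learning-rate
# schedules, seeded fit loop with early stopping, stability reporting,
# animal-level cross-validation, ablation harness and grid search.

#' Learnable per-task log-variances of the multi-task loss
#'
#' @param init_value common initial value (equal initialization gives the
#'   four targets similar weights at the start of training).
#' @export
task_logvars <- function(init_value = -0.5) {
  structure(stats::setNames(rep(init_value, 4), TARGETS),
            init_value = init_value, class = "task_logvars")
}

#' Homoscedastic task-uncertainty weighted multi-task loss
#'
#' `loss = sum_t exp(-s_t) * mse_t + s_t`, where `s_t` is the learnable
#' log-variance of task t. With all `s_t = 0` this reduces to the plain
#' sum of per-task MSEs; the gradient in `s_t` vanishes at
#' `s_t = log(mse_t)`, so tasks with large errors are automatically
#' down-weighted.
#'
#' @param mse non-negative per-task mean squared errors (length 4).
#' @param logvars a [task_logvars()] or numeric vector of length 4.
#' @return scalar loss.
#' @export
uncertainty_weighted_loss <- function(mse, logvars) {
  s <- as.numeric(logvars)
  if (length(mse) != length(s))
    ff_stop("mse and logvars lengths differ", class = "ff_argument_error")
  if (any(!is.finite(mse)) || any(!is.finite(s)))
    ff_stop("non-finite loss input", class = "ff_numeric_error")
  if (any(mse < 0))
    ff_stop("mse must be non-negative", class = "ff_argument_error")
  sum(exp(-s) * mse + s)
}

# analytic gradients of the loss
uw_loss_grad_mse <- function(mse, s) exp(-as.numeric(s))
uw_loss_grad_s <- function(mse, s) -exp(-as.numeric(s)) * mse + 1

#' Learning-rate schedule
#'
#' @param type `"step_decay"` (`base * gamma^floor(epoch/step_size)`),
#'   `"cosine"` (`base * (1 + cos(pi * epoch / t_max)) / 2`, clamped at
#'   the horizon) or `"warmup_cosine"` (linear ramp 0 to base over
#'   `warmup_epochs`, then cosine over `t_max`).
#' @param base_lr base learning rate.
#' @param step_size,gamma step-decay parameters.
#' @param t_max cosine horizon in epochs.
#' @param warmup_epochs warmup length.
#' @export
lr_scheduler <- function(type = c("step_decay", "cosine", "warmup_cosine"),
                         base_lr = 1e-3, step_size = 20L, gamma = 0.5,
                         t_max = 95L, warmup_epochs = 5L) {
  structure(list(type = match.arg(type), base_lr = base_lr,
                 step_size = step_size, gamma = gamma, t_max = t_max,
                 warmup_epochs = warmup_epochs), class = "lr_scheduler")
}

#' Learning rate at a given (0-based) epoch
#'
#' @param scheduler an [lr_scheduler()].
#' @param epoch epoch index, 0-based.
#' @export
scheduled_lr <- function(scheduler, epoch) {
  check_count(epoch, "epoch")
  with(scheduler, switch(type,
    step_decay = base_lr * gamma^floor(epoch / step_size),
    cosine = base_lr * (1 + cos(pi * min(epoch, t_max) / t_max)) / 2,
    warmup_cosine = {
      if (epoch < warmup_epochs) base_lr * epoch / warmup_epochs
      else {
        e <- min(epoch - warmup_epochs, t_max)
        base_lr * (1 + cos(pi * e / t_max)) / 2
      }
    }))
}

#' Training configuration
#'
#' @param max_epochs,batch_size epoch and batch limits.
#' @param optimizer `"adam"`, `"adamw"` or `"sgd_momentum"`.
#' @param base_lr base learning rate.
#' @param weight_decay L2 weight decay (decoupled under `"adamw"`).
#' @param scheduler an [lr_scheduler()].
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed seed driving batch shuffling, dropout and stochastic
#'   augmentation (single-threaded runs are bit-reproducible).
#' @param augmentation_mode `"none"`, `"fixed"` (materialized 5-variant
#'   suite) or `"stochastic"` (per-epoch random flip/rotation/brightness).
#' @param logvar_init initial per-task log-variance.
#' @param task_mask logical length-4 vector of trained tasks (single-task
#'   ablations mask all but one).
#' @export
train_config <- function(max_epochs = 30L, batch_size = 16L,
                         optimizer = c("adamw", "adam", "sgd_momentum"),
                         base_lr = 1e-3, weight_decay = 1e-5,
                         scheduler = lr_scheduler("cosine", base_lr = base_lr,
                                                  t_max = max_epochs),
                         patience = 15L, seed = 42L,
                         augmentation_mode = c("none", "fixed", "stochastic"),
                         logvar_init = -0.5,
                         task_mask = rep(TRUE, 4)) {
  optimizer <- match.arg(optimizer)
  augmentation_mode <- match.arg(augmentation_mode)
  check_count(patience, "patience", min = 1L)
  check_scalar_num(base_lr, "base_lr", lo = 1e-12)
  if (!any(task_mask)) ff_stop("task_mask must keep at least one task",
                               class = "ff_validation_error")
  structure(list(max_epochs = check_count(max_epochs, "max_epochs", 1L),
                 batch_size = check_count(batch_size, "batch_size", 1L),
                 optimizer = optimizer, base_lr = base_lr,
                 weight_decay = weight_decay, scheduler = scheduler,
                 patience = as.integer(patience), seed = as.integer(seed),
                 augmentation_mode = augmentation_mode,
                 logvar_init = logvar_init, task_mask = task_mask),
            class = "train_config")
}

#' Build raw training examples from a flock
#'
#' Renders both views of each requested animal and attaches the tabular
#' covariates and the four targets. Examples are ordered by animal id so
#' downstream results are invariant to roster ordering.
#'
#' @param flock a `flock` data frame.
#' @param ids animal ids to include (default: all).
#' @param render_cfg a [render_config()].
#' @param seed render seed.
#' @export
make_examples <- function(flock, ids = flock$animal_id,
                          render_cfg = render_config(), seed = 42L) {
  ids <- sort(ids)
  idx <- match(ids, flock$animal_id)
  if (anyNA(idx)) ff_stop("ids absent from flock", class = "ff_argument_error")
  lapply(idx, function(i) {
    ph <- flock[i, ]
    list(animal_id = ph$animal_id,
         dorsal = render_animal(ph, "dorsal", render_cfg, seed),
         lateral = render_animal(ph, "lateral", render_cfg, seed),
         bcs = ph$bcs, size_category = ph$size_category,
         y = c(ph$live_weight, ph$carcass_weight, ph$fat_mass,
               ph$lean_mass))
  })
}

# expand raw examples with the fixed augmentation suite (same variant
# applied to both views of an animal)
expand_fixed_aug <- function(examples, suite) {
  out <- list()
  for (e in examples) {
    for (v in suite$fixed_variants) {
      e2 <- e
      e2$dorsal <- image_sample(e$animal_id, "dorsal", v,
                                apply_variant(e$dorsal$image, v, suite))
      e2$lateral <- image_sample(e$animal_id, "lateral", v,
                                 apply_variant(e$lateral$image, v, suite))
      out[[length(out) + 1L]] <- e2
    }
  }
  out
}

prepare_all <- function(model, examples) {
  lapply(examples, function(e)
    prepare_example(model, e$dorsal, e$lateral, e$bcs, e$size_category, e$y))
}

#' Fit a model with the uncertainty-weighted multi-task loss
#'
#' Seeded end-to-end: batch shuffling, dropout and stochastic augmentation
#' all derive from `cfg$seed`, so two single-threaded runs with the same
#' configuration produce identical histories. Targets are standardized
#' with training-set moments (stored on the returned model); the loss and
#' the per-task log-variances operate on the standardized scale. Early
#' stopping monitors the validation loss (uncertainty loss with the
#' current frozen log-variances) and restores the best-epoch weights.
#'
#' @param model an `ff_model`.
#' @param train,val raw example sets from [make_examples()]; their animal
#'   sets must be disjoint (animal-level leakage guard).
#' @param cfg a [train_config()].
#' @param suite augmentation suite for `"fixed"`/`"stochastic"` modes.
#' @return an `ff_fit`: list with the trained `model`, the per-epoch
#'   `history`, `best_epoch`, `stopped_epoch` and final `logvars`.
#' @export
fit <- function(model, train, val, cfg = train_config(),
                suite = aug_suite()) {
  if (length(train) == 0)
    ff_stop("empty training set", class = "ff_argument_error")
  tr_ids <- unique(vapply(train, `[[`, character(1), "animal_id"))
  va_ids <- unique(vapply(val, `[[`, character(1), "animal_id"))
  if (length(intersect(tr_ids, va_ids)) > 0)
    ff_stop("train/val animal sets overlap: animal-level leakage",
            class = "ff_validation_error")

  Y <- t(vapply(train, `[[`, numeric(4), "y"))
  model$target_stats <- list(mean = colMeans(Y),
                             sd = pmax(apply(Y, 2, stats::sd), 1e-8))

  if (cfg$augmentation_mode == "fixed")
    train <- expand_fixed_aug(train, suite)

  prep_train <- if (cfg$augmentation_mode == "stochastic") NULL
                else prepare_all(model, train)
  prep_val <- prepare_all(model, val)
  ystd <- function(e) (e$y - model$target_stats$mean) / model$target_stats$sd

  s <- as.numeric(task_logvars(cfg$logvar_init))
  mask <- as.numeric(cfg$task_mask)
  big <- list(net = model$params, logvars = s)
  n_net <- length(unlist(model$params, use.names = FALSE))
  decay_mask <- c(rep(1, n_net), rep(0, 4))
  state <- adam_init(big)

  n_epoch_rows <- cfg$max_epochs
  hist <- vector("list", n_epoch_rows)
  best <- Inf; best_params <- big$net; best_s <- s
  best_epoch <- 0L; wait <- 0L; stopped <- cfg$max_epochs

  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- scheduled_lr(cfg$scheduler, epoch - 1L)
    if (cfg$augmentation_mode == "stochastic") {
      aug <- lapply(train, function(e) {
        e$dorsal$image <- augment_stochastic(e$dorsal$image, suite)
        e$lateral$image <- augment_stochastic(e$lateral$image, suite)
        e
      })
      prep_train <- prepare_all(model, aug)
    }
    ord <- sample(length(prep_train))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))

    ep_loss <- 0; ep_abs <- numeric(4); n_seen <- 0L
    for (bi in batches) {
      B <- length(bi)
      gsum <- NULL
      err_mat <- matrix(0, B, 4)
      caches <- vector("list", B)
      for (j in seq_len(B)) {
        ex <- prep_train[[bi[j]]]
        fw <- model_forward_any(model, ex, train = TRUE)
        err_mat[j, ] <- fw$pred - ystd(ex)
        caches[[j]] <- fw$cache
      }
      mse <- colMeans(err_mat^2) * mask
      wt <- uw_loss_grad_mse(mse, s)
      for (j in seq_len(B)) {
        dpred <- wt * 2 * err_mat[j, ] * mask / B
        bk <- model_backward_any(model, caches[[j]], dpred)
        gsum <- if (is.null(gsum)) bk$grads else tree_add(gsum, bk$grads)
      }
      g_s <- uw_loss_grad_s(mse, s) * mask
      grads <- list(net = gsum, logvars = g_s)
      big <- list(net = model$params, logvars = s)
      upd <- switch(cfg$optimizer,
        adamw = adam_step(big, grads, state, lr, cfg$weight_decay,
                          decay_mask = decay_mask),
        adam = {
          gflat <- unlist(grads, use.names = FALSE) +
            cfg$weight_decay * unlist(big, use.names = FALSE) * decay_mask
          adam_step(big, utils::relist(gflat, grads), state, lr, 0)
        },
        sgd_momentum = sgd_momentum_step(big, grads, state, lr,
                                         cfg$weight_decay))
      state <- upd$state
      model$params <- upd$params$net
      s <- upd$params$logvars
      ep_loss <- ep_loss + uncertainty_weighted_loss(mse, s) * B
      ep_abs <- ep_abs + colSums(abs(err_mat)) * model$target_stats$sd
      n_seen <- n_seen + B
    }

    val_err <- t(vapply(prep_val, function(ex)
      model_forward_any(model, ex, train = FALSE)$pred - ystd(ex),
      numeric(4)))
    val_mse <- colMeans(val_err^2) * mask
    val_loss <- uncertainty_weighted_loss(val_mse, s)
    val_mae <- colMeans(abs(val_err)) * model$target_stats$sd

    row <- c(epoch = epoch, lr = lr, train_loss = ep_loss / n_seen,
             val_loss = val_loss,
             stats::setNames(ep_abs / n_seen, paste0("train_mae_", TARGETS)),
             stats::setNames(val_mae, paste0("val_mae_", TARGETS)))
    hist[[epoch]] <- row

    if (is.finite(val_loss) && val_loss < best - 1e-12) {
      best <- val_loss; best_params <- model$params; best_s <- s
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) { stopped <- epoch; break }
    }
    stopped <- epoch
  }

  model$params <- best_params
  history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null,
                                                       logical(1))]))
  class(history) <- c("train_history", "data.frame")
  structure(list(model = model, history = history,
                 best_epoch = best_epoch, stopped_epoch = stopped,
                 logvars = stats::setNames(best_s, TARGETS),
                 val_loss = best),
            class = "ff_fit")
}

#' @export
print.ff_fit <- function(x, ...) {
  cat(sprintf("<ff_fit> best epoch %d / stopped %d | best val loss %.4f\n",
              x$best_epoch, x$stopped_epoch, x$val_loss))
  invisible(x)
}

#' Generalization-gap stability report over the final training window
#'
#' Mean and SD of the training and validation MAE over the last `window`
#' epochs, plus the generalization gap (validation minus training mean),
#' for every target present in the history.
#'
#' @param history a `train_history` (or any data frame with paired
#'   `train_mae_*` / `val_mae_*` columns).
#' @param window number of final epochs to summarize.
#' @return data frame with one row per target: `train_mean`, `train_sd`,
#'   `val_mean`, `val_sd`, `gap`.
#' @export
stability_report <- function(history, window = 10L) {
  window <- check_count(window, "window", min = 1L)
  if (nrow(history) < window)
    ff_stop("history shorter than the requested window",
            class = "ff_argument_error")
  tail_h <- utils::tail(history, window)
  tr_cols <- grep("^train_mae", names(history), value = TRUE)
  rows <- lapply(tr_cols, function(tc) {
    vc <- sub("^train_mae", "val_mae", tc)
    if (!vc %in% names(history))
      ff_stop("missing matching column ", vc, class = "ff_argument_error")
    tm <- mean(tail_h[[tc]]); vm <- mean(tail_h[[vc]])
    data.frame(target = sub("^train_mae_?", "", tc),
               train_mean = tm, train_sd = stats::sd(tail_h[[tc]]),
               val_mean = vm, val_sd = stats::sd(tail_h[[vc]]),
               gap = vm - tm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Animal-level k-fold cross-validation
#'
#' Folds are assigned at the animal level by [assign_folds()]; each fold
#' in turn is held out entirely (both its views), the model is trained on
#' the remaining animals and evaluated on the held-out fold.
#'
#' @param flock a `flock`.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param k number of folds.
#' @param render_cfg a [render_config()].
#' @param seed fold-assignment and render seed.
#' @return list with `folds` (per-fold metric data frames), `aggregate`
#'   (per-target mean +/- SD of MAE and R^2 across folds) and the
#'   `fold_manifest`.
#' @export
run_cross_validation <- function(flock, model_cfg, train_cfg, k = 10L,
                                 render_cfg = render_config(), seed = 42L) {
  fm <- assign_folds(flock$animal_id, k = k, seed = seed)
  all_ex <- make_examples(flock, render_cfg = render_cfg, seed = seed)
  names(all_ex) <- vapply(all_ex, `[[`, character(1), "animal_id")
  folds <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    hold <- fm$animal_id[fm$fold == f]
    rest <- setdiff(fm$animal_id, hold)
    model <- ff_model(model_cfg, seed = train_cfg$seed)
    ft <- fit(model, all_ex[rest], all_ex[hold], train_cfg)
    ev <- evaluate_model(ft$model, all_ex[hold])
    ev$fold <- f
    folds[[f + 1L]] <- ev
  }
  allm <- do.call(rbind, folds)
  agg <- do.call(rbind, lapply(TARGETS, function(t) {
    sub <- allm[allm$target == t, ]
    data.frame(target = t,
               mae_mean = mean(sub$mae), mae_sd = stats::sd(sub$mae),
               r2_mean = mean(sub$r2), r2_sd = stats::sd(sub$r2),
               stringsAsFactors = FALSE)
  }))
  list(folds = folds, aggregate = agg, fold_manifest = fm)
}

ABLATION_VARIANTS <- c("backbone_swap", "single_task", "image_only",
                       "concat_fusion", "no_aug_no_reg")

# build the (model, train_cfg, image_only) setup for one ablation variant
ablation_setup <- function(variant, model_cfg, train_cfg) {
  image_only <- FALSE
  switch(variant,
    full = NULL,
    backbone_swap = {
      model_cfg <- model_config("baseline_concat",
                                image_size = model_cfg$image_size,
                                tabular_mlp_widths = model_cfg$tabular_mlp_widths,
                                dropout = model_cfg$dropout)
    },
    single_task = NULL,  # handled by the caller (one fit per task)
    image_only = { image_only <- TRUE },
    concat_fusion = {
      if (model_cfg$family == "token_fusion") model_cfg$fusion <- "concat"
      else model_cfg <- model_config("baseline_concat",
                                     image_size = model_cfg$image_size,
                                     tabular_mlp_widths = model_cfg$tabular_mlp_widths,
                                     dropout = model_cfg$dropout)
    },
    no_aug_no_reg = {
      model_cfg$dropout <- 0
      train_cfg$weight_decay <- 0
      train_cfg$augmentation_mode <- "none"
    },
    ff_stop("unknown ablation variant: ", variant,
            class = "ff_argument_error"))
  list(model_cfg = model_cfg, train_cfg = train_cfg, image_only = image_only)
}

#' Ablation harness
#'
#' Trains the full model plus each requested variant under identical seed,
#' splits and augmentation parameters, and reports MAE/R^2 per target per
#' variant. Variants: `backbone_swap` (convolutional backbone in place of
#' the token-fusion encoder), `single_task` (one independent model per
#' target), `image_only` (tabular branch zeroed), `concat_fusion`
#' (token-level fusion replaced by feature concatenation),
#' `no_aug_no_reg` (no augmentation, dropout or weight decay).
#'
#' @param flock a `flock`.
#' @param model_cfg,train_cfg base configuration (the "full" row).
#' @param variants subset of the variant names above (possibly empty).
#' @param render_cfg a [render_config()].
#' @param seed split/render seed.
#' @return data frame: one row per variant x target with `mae`, `r2` and
#'   the variant's configuration summary.
#' @export
run_ablation <- function(flock, model_cfg, train_cfg,
                         variants = character(0),
                         render_cfg = render_config(), seed = 42L) {
  bad <- setdiff(variants, ABLATION_VARIANTS)
  if (length(bad) > 0)
    ff_stop("unknown ablation variant: ", paste(bad, collapse = ", "),
            class = "ff_argument_error")
  split <- partition_animals(flock$animal_id, seed = seed)
  ids <- split(split$animal_id, split$partition)
  ex <- list(train = make_examples(flock, ids$train, render_cfg, seed),
             val = make_examples(flock, ids$val, render_cfg, seed),
             test = make_examples(flock, ids$test, render_cfg, seed))

  eval_variant <- function(variant) {
    if (variant == "single_task") {
      per_task <- lapply(seq_len(4), function(t) {
        tc <- train_cfg
        tc$task_mask <- seq_len(4) == t
        model <- ff_model(model_cfg, seed = train_cfg$seed)
        ft <- fit(model, ex$train, ex$val, tc)
        evaluate_model(ft$model, ex$test)[t, ]
      })
      return(do.call(rbind, per_task))
    }
    su <- ablation_setup(variant, model_cfg, train_cfg)
    model <- ff_model(su$model_cfg, seed = train_cfg$seed,
                      image_only = su$image_only)
    ft <- fit(model, ex$train, ex$val, su$train_cfg)
    evaluate_model(ft$model, ex$test)
  }

  rows <- lapply(c("full", variants), function(v) {
    m <- eval_variant(v)
    m$variant <- v
    m
  })
  out <- do.call(rbind, rows)
  out[, c("variant", "target", "mae", "rmse", "r2", "mape")]
}

#' Exhaustive grid search over a discrete hyperparameter space
#'
#' Evaluates every combination and returns the configuration with the
#' lowest mean validation MAE averaged across all targets; ties are broken
#' by first-seen order. Non-finite scores (diverged runs) never win.
#'
#' @param space named list of value vectors (names must be
#'   [train_config()] fields such as `base_lr`, `batch_size`,
#'   `weight_decay`, or `dropout` for the model).
#' @param model_cfg,train_cfg base configurations.
#' @param train,val raw example sets (ignored when `eval_fn` is given).
#' @param eval_fn optional `function(config_row)` returning the validation
#'   score (injectable for testing; defaults to training via [fit()]).
#' @return list with `best` (named list of winning values), `scores`
#'   (data frame of all combinations), `best_index`.
#' @export
grid_search <- function(space, model_cfg = NULL, train_cfg = NULL,
                        train = NULL, val = NULL, eval_fn = NULL) {
  if (length(space) == 0 || prod(lengths(space)) == 0)
    ff_stop("empty search space", class = "ff_argument_error")
  grid <- expand.grid(space, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (is.null(eval_fn)) {
    eval_fn <- function(row) {
      mc <- model_cfg; tc <- train_cfg
      for (nm in names(row)) {
        if (nm %in% names(tc)) tc[[nm]] <- row[[nm]]
        else if (nm %in% names(mc)) mc[[nm]] <- row[[nm]]
        else ff_stop("unknown search field: ", nm,
                     class = "ff_argument_error")
      }
      tc$scheduler$base_lr <- tc$base_lr
      model <- ff_model(mc, seed = tc$seed)
      ft <- tryCatch(fit(model, train, val, tc), error = function(e) NULL)
      if (is.null(ft)) return(Inf)
      hb <- ft$history[ft$history$epoch == ft$best_epoch, ]
      mean(as.numeric(hb[paste0("val_mae_", TARGETS)]))
    }
  }
  scores <- vapply(seq_len(nrow(grid)), function(i)
    as.numeric(eval_fn(as.list(grid[i, , drop = FALSE]))), numeric(1))
  scores[!is.finite(scores)] <- Inf
  best_i <- which.min(scores)  # first-seen on ties
  grid$score <- scores
  list(best = as.list(grid[best_i, setdiff(names(grid), "score"),
                           drop = FALSE]),
       scores = grid, best_index = best_i)
}

#' Repeated training runs with derived initialization seeds
#'
#' Trains `n_runs` replicates that share every setting except the weight
#' initialization seed (derived deterministically from the base seed) and
#' reports the spread of the best-epoch validation MAE - the multi-run
#' stability protocol.
#'
#' @param model_cfg,train_cfg configurations.
#' @param train,val raw example sets.
#' @param n_runs number of replicates.
#' @return data frame with one row per run plus attributes `mae_sd`
#'   (per-target SD across runs).
#' @export
run_repeated_training <- function(model_cfg, train_cfg, train, val,
                                  n_runs = 5L) {
  rows <- lapply(seq_len(n_runs), function(r) {
    init_seed <- (train_cfg$seed + 7919L * r) %% 2147483647L
    model <- ff_model(model_cfg, seed = init_seed)
    ft <- fit(model, train, val, train_cfg)
    hb <- ft$history[ft$history$epoch == ft$best_epoch, ]
    data.frame(run = r, init_seed = init_seed,
               stats::setNames(as.list(as.numeric(
                 hb[paste0("val_mae_", TARGETS)])),
                 paste0("val_mae_", TARGETS)))
  })
  out <- do.call(rbind, rows)
  attr(out, "mae_sd") <- apply(out[paste0("val_mae_", TARGETS)], 2,
                               stats::sd)
  out
}
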