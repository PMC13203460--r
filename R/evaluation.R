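# Regression metrics and agreement statistics.

TARGETS <- c("live_weight", "carcass_weight", "fat_mass", "lean_mass")

#' Regression error metrics
#'
#' MAE, RMSE, coefficient of determination (R^2 = 1 - SSE/SST about the
#' truth mean, which may be negative and is not the squared correlation),
#' and MAPE in percent.
#'
#' @param y truth vector (strictly positive for MAPE).
#' @param yhat prediction vector of equal length.
#' @return list of class `metric_set` with `mae`, `rmse`, `r2`, `mape`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat))
    ff_stop("y and yhat must have equal length", class = "ff_argument_error")
  if (length(y) < 2)
    ff_stop("need at least 2 observations", class = "ff_argument_error")
  if (any(y == 0))
    ff_stop("MAPE undefined: y contains zeros", class = "ff_argument_error")
  e <- yhat - y
  structure(list(mae = mean(abs(e)),
                 rmse = sqrt(mean(e^2)),
                 r2 = 1 - sum(e^2) / sum((y - mean(y))^2),
                 mape = 100 * mean(abs(e / y))),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("MAE %.3f | RMSE %.3f | R2 %.3f | MAPE %.2f%%\n",
              x$mae, x$rmse, x$r2, x$mape))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(y, yhat) / (var(y) + var(yhat) + (mean y - mean yhat)^2)`
#' with population (1/n) moments - the standard Lin definition. Penalizes
#' both dispersion and location shift from the identity line, so
#' `|CCC| <= |r|`.
#'
#' @param y,yhat equal-length non-constant vectors.
#' @export
lin_ccc <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    ff_stop("y and yhat must have equal length >= 2",
            class = "ff_argument_error")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    ff_stop("CCC undefined for constant vectors", class = "ff_argument_error")
  n <- length(y)
  vy <- mean((y - mean(y))^2)
  vh <- mean((yhat - mean(yhat))^2)
  cyh <- mean((y - mean(y)) * (yhat - mean(yhat)))
  2 * cyh / (vy + vh + (mean(y) - mean(yhat))^2)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `yhat - y`; the bias is their mean, the limits of
#' agreement are `bias +/- 1.96 * SD` with the sample (n-1) SD. The slope
#' of the differences against the pair means is reported as a
#' proportional-bias diagnostic.
#'
#' @param y,yhat equal-length vectors (n >= 2).
#' @return list of class `ba_stats` with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `prop_bias_slope`.
#' @export
bland_altman <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    ff_stop("need paired vectors of length >= 2", class = "ff_argument_error")
  d <- yhat - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  m <- (y + yhat) / 2
  slope <- if (stats::sd(m) == 0) 0
           else unname(stats::coef(stats::lm(d ~ m))[2])
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 prop_bias_slope = slope),
            class = "ba_stats")
}

#' @export
print.ba_stats <- function(x, ...) {
  cat(sprintf("bias %+.3f kg | LoA [%.3f, %.3f] | SD %.3f | prop-bias slope %.4f\n",
              x$bias, x$loa_low, x$loa_high, x$sd_diff, x$prop_bias_slope))
  invisible(x)
}

# ---- Wilcoxon signed-rank with exact tie-aware null ------------------------

# Exact two-sided signed-rank test. Zero differences are dropped; ties get
# average ranks. For n <= exact_max the null distribution of W+ is built by
# dynamic-programming convolution over doubled ranks (average ranks are
# multiples of 1/2, so doubling makes them integers); beyond that a normal
# approximation with tie-corrected variance and continuity correction is
# used.
wilcoxon_signed_rank <- function(d, exact_max = 25L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                method = "no non-zero differences"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # f[k+1] = number of sign assignments with doubled rank-sum k
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1 - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Compare two models' absolute errors with paired tests
#'
#' Runs a paired t-test and a Wilcoxon signed-rank test on
#' `errA - errB` (two-sided). The signed-rank test drops zero differences,
#' uses average ranks for ties, and an exact tie-aware null for n <= 25
#' (normal approximation with continuity correction beyond).
#'
#' @param errA,errB paired absolute-error vectors (length >= 5).
#' @return list with `t_statistic`, `t_p`, `wilcoxon_statistic`,
#'   `wilcoxon_p`, `mean_diff`, `n`.
#' @export
compare_models_errors <- function(errA, errB) {
  if (length(errA) != length(errB) || length(errA) < 5)
    ff_stop("need paired vectors of length >= 5", class = "ff_argument_error")
  d <- errA - errB
  if (all(d == 0)) {
    return(list(t_statistic = 0, t_p = 1,
                wilcoxon_statistic = NA_real_, wilcoxon_p = NA_real_,
                mean_diff = 0, n = length(d),
                note = "all differences zero: no evidence of any difference"))
  }
  tt <- stats::t.test(errA, errB, paired = TRUE)
  wx <- wilcoxon_signed_rank(d)
  list(t_statistic = unname(tt$statistic), t_p = tt$p.value,
       wilcoxon_statistic = wx$statistic, wilcoxon_p = wx$p_value,
       mean_diff = mean(d), n = length(d))
}

#' Per-target evaluation of a trained model on held-out animals
#'
#' @param model a trained `ff_model`.
#' @param examples an example set (see [make_examples()]).
#' @return data frame with one row per target: `mae`, `rmse`, `r2`, `mape`
#'   plus a `predictions` attribute (n x 4 matrix).
#' @export
evaluate_model <- function(model, examples) {
  if (length(examples) == 0)
    ff_stop("empty evaluation set", class = "ff_argument_error")
  preds <- t(vapply(examples, function(e)
    forward_multitarget(model, e$dorsal, e$lateral, e$bcs, e$size_category),
    numeric(4)))
  truth <- t(vapply(examples, function(e) e$y, numeric(4)))
  rows <- lapply(seq_along(TARGETS), function(j) {
    m <- regression_metrics(truth[, j], preds[, j])
    data.frame(target = TARGETS[j], mae = m$mae, rmse = m$rmse, r2 = m$r2,
               mape = m$mape, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- preds
  attr(out, "truth") <- truth
  out
}
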