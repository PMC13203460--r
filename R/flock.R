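# Synthetic flock generation: phenotypically coherent animals whose four
# regression targets satisfy mass conservation by construction.

#' Sample a synthetic flock
#'
#' Draws `n` animals from the calibrated population. Live weight follows a
#' normal distribution truncated to the calibrated bounds (sampled by
#' rejection, with parent parameters corrected so the *truncated* moments
#' match the calibration mean/SD). Fat mass follows a lognormal sharing a
#' latent Gaussian factor with live weight (correlation
#' `calib$fm_lw_corr`), truncated to its bounds and additionally capped at
#' `fm_cap_fraction * carcass_weight`. Carcass weight is
#' `dressing_fraction * live_weight` plus a small noise; bone mass is a
#' fixed fraction of carcass weight and lean mass is the remainder, so
#' `fat + lean + bone == carcass` holds exactly for every animal.
#'
#' Each animal draws from its own random stream derived from
#' `(seed, animal_id)`, so the flock is reproducible field-by-field and
#' independent of processing order.
#'
#' @param n number of animals (>= 0).
#' @param seed integer seed.
#' @param calib a [flock_calibration()].
#' @return a `data.frame` of class `flock`, one row per animal, with columns
#'   `animal_id`, `live_weight`, `carcass_weight`, `fat_mass`, `lean_mass`,
#'   `bone_mass`, `bcs`, `size_category` (all masses in kg).
#' @export
sample_flock <- function(n, seed = 42L, calib = flock_calibration()) {
  n <- check_count(n, "n")
  validate_calibration(calib)
  ids <- if (n > 0) sprintf("A%04d", seq_len(n)) else character(0)

  lw <- cw <- fm <- numeric(n)
  rho <- calib$fm_lw_corr
  for (i in seq_len(n)) {
    draws <- with_stream(seed, ids[i], {
      # live weight first (rejection on its own latent only, so the live
      # weight marginal is exactly the truncated normal), then fat mass
      # conditional on the accepted latent
      z1 <- NA_real_; lw_i <- NA_real_
      for (iter in 1:1000) {
        z1 <- stats::rnorm(1)
        lw_i <- calib$lw_parent_mu + calib$lw_parent_sigma * z1
        if (lw_i >= calib$lw_min && lw_i <= calib$lw_max) break
        lw_i <- NA_real_
      }
      fm_i <- NA_real_
      for (iter in 1:1000) {
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
        fm_i <- exp(calib$fm_logmean + calib$fm_logsd * z2)
        if (fm_i >= calib$fm_min && fm_i <= calib$fm_max) break
        fm_i <- NA_real_
      }
      if (is.na(lw_i) || is.na(fm_i))
        ff_stop("rejection sampling failed to land in bounds",
                class = "ff_validation_error")
      cw_i <- calib$dressing_fraction * lw_i +
        stats::rnorm(1, 0, calib$cw_noise_sd)
      c(lw_i, cw_i, fm_i)
    })
    lw[i] <- draws[1]
    cw[i] <- min(max(draws[2], 0.1), 0.95 * draws[1])  # carcass < live weight
    fm[i] <- min(draws[3], calib$fm_cap_fraction * cw[i])
  }

  bone <- calib$bone_fraction * cw
  lean <- cw - fm - bone
  flock <- data.frame(animal_id = ids, live_weight = lw, carcass_weight = cw,
                      fat_mass = fm, lean_mass = lean, bone_mass = bone,
                      bcs = rep(NA_real_, n),
                      size_category = rep(NA_character_, n),
                      stringsAsFactors = FALSE)
  class(flock) <- c("flock", "data.frame")
  if (n >= 1) {
    tab <- tabular_covariates(flock)
    flock$bcs <- tab$bcs
    flock$size_category <- tab$size_category
  }
  flock
}

# Rank-based covariates for a whole flock. BCS maps the rank-quantile of the
# fat ratio (fat mass / carcass weight) onto the 1.0-5.0 half-point scale;
# size categories are live-weight tertiles. Ties broken by animal_id.
tabular_covariates <- function(flock) {
  n <- nrow(flock)
  ratio <- flock$fat_mass / flock$carcass_weight
  ord <- order(ratio, flock$animal_id)
  rank_ratio <- integer(n); rank_ratio[ord] <- seq_len(n)
  q <- if (n == 1) 0.5 else (rank_ratio - 1) / (n - 1)
  bcs <- pmin(5, pmax(1, round((1 + 4 * q) * 2) / 2))

  ord_lw <- order(flock$live_weight, flock$animal_id)
  rank_lw <- integer(n); rank_lw[ord_lw] <- seq_len(n)
  n_small <- round(n / 3)
  size <- ifelse(rank_lw <= n_small, "small",
                 ifelse(rank_lw > n - n_small, "large", "medium"))
  list(bcs = bcs, size_category = size)
}

#' Derive the tabular covariates of one animal within its flock
#'
#' Body condition score is `1 + 4 * q` where `q` is the rank-quantile of
#' the animal's fat ratio (fat/carcass) within the flock, rounded to the
#' nearest 0.5 and clamped to the 1-5 scale; the size category comes from
#' live-weight tertiles (lower third `small`, upper third `large`).
#'
#' @param ph one-row `data.frame` (a row of a flock) or an `animal_id`
#'   present in `flock`.
#' @param flock a `flock` data frame with at least 3 animals.
#' @return list with elements `bcs` and `size_category`.
#' @export
derive_tabular <- function(ph, flock) {
  if (nrow(flock) < 3)
    ff_stop("flock must contain at least 3 animals (tertiles undefined)",
            class = "ff_validation_error")
  id <- if (is.character(ph)) ph else ph$animal_id
  idx <- match(id, flock$animal_id)
  if (is.na(idx))
    ff_stop("animal ", id, " not found in flock", class = "ff_validation_error")
  tab <- tabular_covariates(flock)
  list(bcs = tab$bcs[idx], size_category = tab$size_category[idx])
}

#' @export
print.flock <- function(x, ...) {
  cat(sprintf("<flock> %d animals\n", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf("  live weight: %.1f-%.1f kg (mean %.1f, SD %.1f)\n",
                min(x$live_weight), max(x$live_weight),
                mean(x$live_weight), stats::sd(x$live_weight)))
    cat(sprintf("  fat mass   : %.2f-%.2f kg\n",
                min(x$fat_mass), max(x$fat_mass)))
  }
  NextMethod()
}

#' Write / read a flock manifest CSV
#'
#' @param flock a `flock` data frame.
#' @param path CSV path.
#' @return `read_flock_csv` returns the `flock`; `write_flock_csv` returns
#'   `path` invisibly.
#' @export
write_flock_csv <- function(flock, path) {
  utils::write.csv(as.data.frame(flock), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_flock_csv
#' @export
read_flock_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("animal_id", "live_weight", "carcass_weight", "fat_mass",
            "lean_mass", "bone_mass", "bcs", "size_category")
  if (!all(need %in% names(df)))
    ff_stop("flock CSV is missing columns: ",
            paste(setdiff(need, names(df)), collapse = ", "),
            class = "ff_parse_error")
  if (anyDuplicated(df$animal_id))
    ff_stop("duplicated animal_id in flock CSV", class = "ff_parse_error")
  class(df) <- c("flock", "data.frame")
  df
}
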