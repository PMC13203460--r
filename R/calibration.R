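# Flock calibration: the population the synthetic generator emulates.

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' parent parameters `mu`, `sigma` truncated to `[lo, hi]`.
#'
#' @param mu,sigma parent (pre-truncation) mean and SD.
#' @param lo,hi truncation bounds.
#' @return named numeric vector with elements `mean` and `sd`.
#' @export
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (a * pa - b * pb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Solve for parent (mu, sigma) so that the truncated distribution has the
# requested mean and SD. Truncation shrinks the SD and can shift the mean,
# so sampling from N(mean, sd) truncated to the bounds would not reproduce
# the published moments; this correction makes it exact in expectation.
truncnorm_parent_params <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mo["mean"] - mean)^2 + (mo["sd"] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-8)
    ff_stop("could not match truncated-normal moments for the given bounds",
            class = "ff_validation_error")
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Calibration of the synthetic flock generator
#'
#' Houses the population moments and trait bounds the generator reproduces
#' (live weight mean 62.4 kg, SD 8.7 kg, range 48.0-88.5 kg; fat mass range
#' 0.88-17.64 kg) together with the biological plumbing constants: the
#' lognormal fat-mass law, the latent correlation between live weight and
#' fat mass, the dressing-out fraction mapping live weight to carcass
#' weight, the bone fraction of the carcass, and the hard cap on fat mass
#' as a fraction of carcass weight which guarantees positive lean mass.
#'
#' @param lw_mean,lw_sd target mean and SD of live weight (kg) after
#'   truncation.
#' @param lw_min,lw_max truncation bounds for live weight (kg).
#' @param fm_logmean,fm_logsd parameters of the lognormal fat-mass law
#'   (log-kg scale).
#' @param fm_min,fm_max truncation bounds for fat mass (kg).
#' @param fm_lw_corr latent Gaussian correlation between live weight and fat
#'   mass, in \[-1, 1\].
#' @param dressing_fraction carcass weight as a fraction of live weight.
#' @param cw_noise_sd SD (kg) of the noise on carcass weight around
#'   `dressing_fraction * live_weight`.
#' @param bone_fraction bone mass as a fraction of carcass weight.
#' @param fm_cap_fraction upper cap on fat mass as a fraction of carcass
#'   weight; together with `bone_fraction` it must leave room for lean mass.
#' @return an object of class `flock_calibration`.
#' @export
flock_calibration <- function(lw_mean = 62.4, lw_sd = 8.7,
                              lw_min = 48.0, lw_max = 88.5,
                              fm_logmean = log(5.5), fm_logsd = 0.55,
                              fm_min = 0.88, fm_max = 17.64,
                              fm_lw_corr = 0.6,
                              dressing_fraction = 0.44,
                              cw_noise_sd = 0.5,
                              bone_fraction = 0.18,
                              fm_cap_fraction = 0.55) {
  calib <- structure(
    list(lw_mean = lw_mean, lw_sd = lw_sd, lw_min = lw_min, lw_max = lw_max,
         fm_logmean = fm_logmean, fm_logsd = fm_logsd,
         fm_min = fm_min, fm_max = fm_max, fm_lw_corr = fm_lw_corr,
         dressing_fraction = dressing_fraction, cw_noise_sd = cw_noise_sd,
         bone_fraction = bone_fraction, fm_cap_fraction = fm_cap_fraction),
    class = "flock_calibration")
  validate_calibration(calib)
  parent <- truncnorm_parent_params(lw_mean, lw_sd, lw_min, lw_max)
  calib$lw_parent_mu <- unname(parent["mu"])
  calib$lw_parent_sigma <- unname(parent["sigma"])
  calib
}

validate_calibration <- function(calib) {
  if (!inherits(calib, "flock_calibration"))
    ff_stop("not a flock_calibration object", class = "ff_validation_error")
  with(calib, {
    if (!(lw_min < lw_mean && lw_mean < lw_max))
      ff_stop("live-weight bounds must bracket the mean",
              class = "ff_validation_error")
    if (!(fm_min < fm_max))
      ff_stop("fat-mass bounds must satisfy fm_min < fm_max",
              class = "ff_validation_error")
    if (!(lw_sd > 0 && fm_logsd > 0 && cw_noise_sd >= 0))
      ff_stop("scale parameters must be positive",
              class = "ff_validation_error")
    if (!(dressing_fraction > 0 && dressing_fraction < 1))
      ff_stop("dressing_fraction must be in (0, 1)",
              class = "ff_validation_error")
    if (!(bone_fraction > 0 && fm_cap_fraction > 0 &&
          bone_fraction + fm_cap_fraction < 1))
      ff_stop("bone_fraction + fm_cap_fraction must be < 1 (lean mass must stay positive)",
              class = "ff_validation_error")
    if (abs(fm_lw_corr) > 1)
      ff_stop("fm_lw_corr must be in [-1, 1]", class = "ff_validation_error")
  })
  invisible(calib)
}

#' @export
print.flock_calibration <- function(x, ...) {
  cat("<flock_calibration>\n")
  cat(sprintf("  live weight : mean %.1f kg, SD %.1f kg, bounds [%.1f, %.1f]\n",
              x$lw_mean, x$lw_sd, x$lw_min, x$lw_max))
  cat(sprintf("  fat mass    : lognormal(%.3f, %.2f), bounds [%.2f, %.2f]\n",
              x$fm_logmean, x$fm_logsd, x$fm_min, x$fm_max))
  cat(sprintf("  latent corr %.2f | dressing %.2f | bone %.2f | fat cap %.2f\n",
              x$fm_lw_corr, x$dressing_fraction, x$bone_fraction,
              x$fm_cap_fraction))
  invisible(x)
}
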