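# Rendering: paired dorsal/lateral rasters whose geometry encodes the
# regression targets. Deliberately schematic (two-lobed body silhouette,
# red reference marker, additive noise) - the point is decodability of the
# targets from geometry, not photorealism.

#' Rendering configuration
#'
#' @param image_size side of the square raster in pixels (>= 32).
#' @param marker_length length in pixels of the red reference bar (stands in
#'   for the 40 cm field marker used for scale).
#' @param background_noise_sd,texture_noise_sd SDs (intensity units on the
#'   \[0,1\] scale) of additive background and fleece-texture noise.
#' @param width_coeffs per-view `(intercept, lw_slope, fm_slope)` in pixels,
#'   pixels/kg live weight and pixels/kg fat mass: the body half-width is
#'   `intercept + lw_slope * LW + fm_slope * modifier(size) * FM`. Defaults
#'   scale linearly with `image_size` from a 64-pixel reference.
#' @param fm_size_modifier named multipliers of the fat-mass slope per size
#'   category. Because the multiplier depends on the size category, fat
#'   mass is not identifiable from the image alone - the tabular branch is
#'   genuinely informative (this is what makes multimodal fusion testable
#'   on synthetic data).
#' @return object of class `render_config`.
#' @export
render_config <- function(image_size = 64L,
                          marker_length = max(4L, round(image_size / 5)),
                          background_noise_sd = 0.01,
                          texture_noise_sd = 0.02,
                          width_coeffs = NULL,
                          fm_size_modifier = c(small = 1.6, medium = 1.0,
                                               large = 0.4)) {
  image_size <- check_count(image_size, "image_size", min = 32L)
  marker_length <- check_count(marker_length, "marker_length", min = 1L)
  if (marker_length >= image_size)
    ff_stop("marker_length must be smaller than image_size",
            class = "ff_validation_error")
  s <- image_size / 64
  if (is.null(width_coeffs)) {
    width_coeffs <- list(
      dorsal  = c(intercept = 3 * s, lw_slope = 0.25 * s, fm_slope = 0.08 * s),
      lateral = c(intercept = 4 * s, lw_slope = 0.16 * s, fm_slope = 0.16 * s))
  }
  structure(list(image_size = image_size, marker_length = marker_length,
                 background_noise_sd = background_noise_sd,
                 texture_noise_sd = texture_noise_sd,
                 width_coeffs = width_coeffs,
                 fm_size_modifier = fm_size_modifier,
                 background_level = 0.30,
                 body_level = c(0.80, 0.78, 0.74)),
            class = "render_config")
}

body_half_width <- function(ph, view, cfg) {
  co <- cfg$width_coeffs[[view]]
  mod <- cfg$fm_size_modifier[[ph$size_category]]
  unname(co["intercept"] + co["lw_slope"] * ph$live_weight +
           co["fm_slope"] * mod * ph$fat_mass)
}

#' Body silhouette mask for a phenotype
#'
#' Logical H x W matrix marking the two-lobed (thoracic + rump) body
#' silhouette the renderer draws for this phenotype and view. Exported
#' because it defines the "body region" used by the explainability checks.
#'
#' @param ph a one-row flock data frame (needs `live_weight`, `fat_mass`,
#'   `size_category`).
#' @param view `"dorsal"` or `"lateral"`.
#' @param cfg a [render_config()].
#' @export
body_mask <- function(ph, view = c("dorsal", "lateral"),
                      cfg = render_config()) {
  view <- match.arg(view)
  H <- cfg$image_size
  b <- body_half_width(ph, view, cfg)
  if (b >= 0.47 * H)
    ff_stop("phenotype too large for the frame (half-width ", round(b, 1),
            " px at image size ", H, ")", class = "ff_render_error")
  row_c <- if (view == "dorsal") 0.50 * H else 0.55 * H
  lobes <- list(c(col = 0.38 * H, a = 0.28 * H, bfac = 1.00),
                c(col = 0.66 * H, a = 0.20 * H, bfac = 0.88))
  rows <- matrix(seq_len(H), H, H)
  cols <- matrix(seq_len(H), H, H, byrow = TRUE)
  mask <- matrix(FALSE, H, H)
  for (lb in lobes) {
    mask <- mask |
      (((cols - lb["col"]) / lb["a"])^2 +
         ((rows - row_c) / (b * lb["bfac"]))^2) <= 1
  }
  mask
}

#' Render one view of one animal
#'
#' Deterministic given `(ph, view, cfg, seed)`: the body silhouette from
#' [body_mask()] is drawn over a flat background, additive Gaussian noise is
#' applied (background and fleece-texture SDs from the config), the raster
#' is clipped to \[0,1\] and a pure-red reference bar of `marker_length`
#' pixels is stamped in the top-left corner. Refuses phenotypes whose body
#' would overflow the frame.
#'
#' @inheritParams body_mask
#' @param seed integer; the noise stream is derived from
#'   `(seed, animal_id, view)` so renders are order-independent.
#' @return an `image_sample` (see [image_sample()]), `augtag = "original"`.
#' @export
render_animal <- function(ph, view = c("dorsal", "lateral"),
                          cfg = render_config(), seed = 42L) {
  view <- match.arg(view)
  H <- cfg$image_size
  mask <- body_mask(ph, view, cfg)
  img <- array(cfg$background_level, c(H, H, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- cfg$body_level[ch]
    img[, , ch] <- plane
  }
  if (cfg$background_noise_sd > 0 || cfg$texture_noise_sd > 0) {
    noise <- with_stream(seed, paste(ph$animal_id, view, sep = "/"), {
      bg <- if (cfg$background_noise_sd > 0)
        stats::rnorm(H * H * 3, 0, cfg$background_noise_sd) else numeric(H * H * 3)
      tx <- if (cfg$texture_noise_sd > 0)
        stats::rnorm(H * H * 3, 0, cfg$texture_noise_sd) else numeric(H * H * 3)
      list(bg = array(bg, c(H, H, 3)), tx = array(tx, c(H, H, 3)))
    })
    mask3 <- array(rep(mask, 3), c(H, H, 3))
    img <- img + noise$bg * !mask3 + noise$tx * mask3
  }
  img <- clip01(img)
  # reference marker: pure red bar, rows 3-5, marker_length pixels per row
  mc <- 3:(2 + cfg$marker_length)
  img[3:5, mc, 1] <- 1; img[3:5, mc, 2] <- 0; img[3:5, mc, 3] <- 0
  image_sample(ph$animal_id, view, "original", img)
}

#' One view of one animal
#'
#' @param animal_id animal identifier.
#' @param view `"dorsal"` or `"lateral"`.
#' @param augtag augmentation tag (`"original"` for un-augmented images).
#' @param image H x W x 3 array in \[0,1\].
#' @param path optional source/destination path.
#' @export
image_sample <- function(animal_id, view, augtag, image, path = NULL) {
  check_image(image)
  if (!view %in% c("dorsal", "lateral"))
    ff_stop("view must be 'dorsal' or 'lateral'", class = "ff_argument_error")
  structure(list(animal_id = animal_id, view = view, augtag = augtag,
                 image = image, path = path),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<image_sample> %s %s [%s] %dx%d\n",
              x$animal_id, x$view, x$augtag, d[1], d[2]))
  invisible(x)
}

#' Count body (non-background) pixels of a zero-noise render
#'
#' @param sample an `image_sample` rendered with zero noise.
#' @param cfg the [render_config()] used to render it.
#' @export
body_pixel_count <- function(sample, cfg = render_config()) {
  # body pixels differ from the flat background in the green channel and
  # are not part of the red marker
  g <- sample$image[, , 2]
  sum(abs(g - cfg$background_level) > 1e-6 & g > 0)
}

#' Write an image sample as an 8-bit PNG named `<id>_<view>_<augtag>.png`
#'
#' @param sample an `image_sample`.
#' @param dir output directory (created if missing).
#' @return the file path, invisibly.
#' @export
write_image_png <- function(sample, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_%s.png", sample$animal_id,
                                 sample$view, sample$augtag))
  png::writePNG(sample$image, path)
  invisible(path)
}

#' Render both views of every animal in a flock
#'
#' @param flock a `flock` data frame.
#' @param cfg a [render_config()].
#' @param seed integer noise seed.
#' @return list of `image_sample` (2 per animal, dorsal then lateral).
#' @export
render_flock <- function(flock, cfg = render_config(), seed = 42L) {
  out <- vector("list", 2L * nrow(flock))
  k <- 0L
  for (i in seq_len(nrow(flock))) {
    for (v in c("dorsal", "lateral")) {
      k <- k + 1L
      out[[k]] <- render_animal(flock[i, ], v, cfg, seed)
    }
  }
  out
}
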