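# Grad-CAM adapted to regression outputs, for the convolutional families.

#' Gradient-weighted class activation map for one regression output
#'
#' Channel weights are the spatial means of the gradient of the selected
#' output with respect to the chosen convolutional feature map; the raw
#' map is the rectified weighted channel sum, normalized by its maximum
#' (an identically-zero map stays zero rather than dividing by zero) and
#' upsampled bilinearly to the input resolution.
#'
#' @param model a trained conv-family `ff_model` (`baseline_concat` or
#'   `attention_fusion`; the token-fusion family exposes no convolutional
#'   feature maps).
#' @param dorsal,lateral input `image_sample`s.
#' @param bcs,size_category tabular inputs.
#' @param target_index which output, 1 = live weight, 2 = carcass weight,
#'   3 = fat mass, 4 = lean mass.
#' @param view which view's branch to explain.
#' @param layer_id backbone stage whose post-activation feature map is
#'   used (default: the final convolutional stage).
#' @return a `heatmap`: list with `values` (H x W matrix in \[0,1\] at the
#'   input resolution), `target_index`, `layer_id`, `view`.
#' @export
grad_cam <- function(model, dorsal, lateral, bcs, size_category,
                     target_index = 1L, view = c("dorsal", "lateral"),
                     layer_id = NULL) {
  view <- match.arg(view)
  if (!model$config$family %in% c("baseline_concat", "attention_fusion"))
    ff_stop("Grad-CAM requires a convolutional family model",
            class = "ff_argument_error")
  target_index <- check_count(target_index, "target_index", min = 1L)
  if (target_index > 4)
    ff_stop("target_index must be one of 1..4", class = "ff_argument_error")
  n_stages <- length(model$params$stages)
  layer_id <- layer_id %||% n_stages
  if (layer_id < 1 || layer_id > n_stages)
    ff_stop("layer_id must be in 1..", n_stages, class = "ff_argument_error")

  ex <- prepare_example(model, dorsal, lateral, bcs, size_category)
  fw <- model_forward_any(model, ex, train = FALSE)
  dpred <- as.numeric(seq_len(4) == target_index)
  bk <- model_backward_any(model, fw$cache, dpred, collect = layer_id)
  dA <- bk$collected[[view]]
  A <- if (view == "dorsal") fw$cache$bb_d$caches[[layer_id]]$act_out
       else fw$cache$bb_l$caches[[layer_id]]$act_out

  alpha <- apply(dA, 3, mean)
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) raw <- raw + alpha[k] * A[, , k]
  raw <- pmax(raw, 0)
  mx <- max(raw)
  if (mx > 0) raw <- raw / mx
  size <- model$config$image_size
  up <- EBImage::resize(EBImage::Image(t(raw)), w = size, h = size)
  values <- t(EBImage::imageData(up))
  values <- pmin(pmax(values, 0), 1)
  if (mx == 0) values[] <- 0
  structure(list(values = values, target_index = target_index,
                 layer_id = layer_id, view = view), class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap> %dx%d | target %d | layer %d | %s view | max %.3f\n",
              nrow(x$values), ncol(x$values), x$target_index, x$layer_id,
              x$view, max(x$values)))
  invisible(x)
}

# blue (low) -> red (high) colormap on [0,1]
heat_colormap <- function(v) {
  H <- nrow(v); W <- ncol(v)
  out <- array(0, c(H, W, 3))
  out[, , 1] <- v
  out[, , 2] <- 0.5 * sin(pi * v)
  out[, , 3] <- 1 - v
  out
}

#' Overlay a heatmap on its source image
#'
#' Pixelwise convex blend `(1 - alpha) * image + alpha * colormap(heatmap)`
#' with a blue-to-red colormap (blue = low, red = high attention).
#'
#' @param hm a `heatmap`.
#' @param image an `image_sample` (or H x W x 3 array) matching the
#'   heatmap resolution.
#' @param alpha blend weight in \[0,1\]; 0 returns the source image.
#' @return H x W x 3 RGB array in \[0,1\].
#' @export
overlay_heatmap <- function(hm, image, alpha = 0.5) {
  check_scalar_num(alpha, "alpha", 0, 1)
  img <- if (inherits(image, "image_sample")) image$image else image
  check_image(img)
  if (!all(dim(img)[1:2] == dim(hm$values)))
    ff_stop("heatmap and image shapes differ", class = "ff_argument_error")
  cmap <- heat_colormap(hm$values)
  (1 - alpha) * img + alpha * cmap
}

#' Write a heatmap as a raw CSV grid
#'
#' @param hm a `heatmap`.
#' @param path CSV path.
#' @export
write_heatmap_csv <- function(hm, path) {
  utils::write.table(hm$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
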