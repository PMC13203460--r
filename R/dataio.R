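# Dataset assembly: strict animal-level partitioning, training-only
# augmentation, cross-validation folds, and leakage verification.

#' Partition animals into train/validation/test sets
#'
#' Animals (never individual images) are shuffled deterministically by
#' `seed` and assigned with the rounding rule
#' `train = floor(r_train * n)`, `val = ceil(r_val * n)`,
#' `test = remainder` - the rule that maps 156 animals at 70/15/15 onto
#' 109/24/23.
#'
#' @param ids unique animal identifiers.
#' @param ratios numeric length-3 `(train, val, test)`, summing to 1.
#' @param seed integer shuffle seed.
#' @return a `split_manifest`: data frame `(animal_id, partition)` with the
#'   ratios and seed as attributes.
#' @export
partition_animals <- function(ids, ratios = c(0.70, 0.15, 0.15), seed = 42L) {
  if (anyDuplicated(ids))
    ff_stop("duplicate animal ids", class = "ff_validation_error")
  n <- length(ids)
  if (n < 3) ff_stop("need at least 3 animals", class = "ff_validation_error")
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8)
    ff_stop("ratios must be three fractions summing to 1",
            class = "ff_validation_error")
  n_train <- floor(ratios[1] * n)
  n_val <- ceiling(ratios[2] * n)
  n_test <- n - n_train - n_val
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  manifest <- data.frame(
    animal_id = shuffled,
    partition = rep(c("train", "val", "test"), c(n_train, n_val, n_test)),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$animal_id), , drop = FALSE]
  rownames(manifest) <- NULL
  structure(manifest, ratios = ratios, seed = as.integer(seed),
            class = c("split_manifest", "data.frame"))
}

#' Assign animals to cross-validation folds
#'
#' Deterministic shuffle then round-robin assignment; fold sizes differ by
#' at most one. All images of an animal inherit its fold.
#'
#' @param ids unique animal identifiers.
#' @param k number of folds (2 <= k <= length(ids)).
#' @param seed integer shuffle seed.
#' @return a `fold_manifest`: data frame `(animal_id, fold)` with folds in
#'   `0..k-1`, `k` and `seed` as attributes.
#' @export
assign_folds <- function(ids, k = 10L, seed = 42L) {
  if (anyDuplicated(ids))
    ff_stop("duplicate animal ids", class = "ff_validation_error")
  k <- check_count(k, "k", min = 2L)
  n <- length(ids)
  if (k > n) ff_stop("k must not exceed the number of animals",
                     class = "ff_validation_error")
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  manifest <- data.frame(animal_id = shuffled,
                         fold = (seq_len(n) - 1L) %% k,
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$animal_id), , drop = FALSE]
  rownames(manifest) <- NULL
  structure(manifest, k = k, seed = as.integer(seed),
            class = c("fold_manifest", "data.frame"))
}

# ---- augmentation ----------------------------------------------------------

#' Augmentation suite
#'
#' The deterministic fixed suite materializes exactly five variants per
#' image (original, horizontal flip, +rotation, -rotation, +brightness);
#' the stochastic parameters drive optional on-the-fly per-epoch
#' augmentation during training.
#'
#' @param flip_prob probability of a horizontal flip (stochastic mode).
#' @param rotation_deg rotation amplitude in degrees (+/-).
#' @param brightness_delta multiplicative brightness amplitude (+/-).
#' @export
aug_suite <- function(flip_prob = 0.5, rotation_deg = 8,
                      brightness_delta = 0.2) {
  check_scalar_num(flip_prob, "flip_prob", 0, 1)
  structure(list(flip_prob = flip_prob, rotation_deg = rotation_deg,
                 brightness_delta = brightness_delta,
                 fixed_variants = c("original", "hflip", "rot_plus",
                                    "rot_minus", "bright_up")),
            class = "aug_suite")
}

# rotate an H x W x 3 array about its centre, filling exposed corners with
# the image's border colour (EBImage uses x,y order, hence the aperm pair)
rotate_image <- function(img, degrees) {
  H <- dim(img)[1]; W <- dim(img)[2]
  border <- rbind(img[1, , ], img[H, , ], img[, 1, ], img[, W, ])
  fill <- grDevices::rgb(stats::median(border[, 1]),
                         stats::median(border[, 2]),
                         stats::median(border[, 3]))
  ebi <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  rot <- EBImage::rotate(ebi, degrees, bg.col = fill, output.dim = c(W, H))
  clip01(aperm(EBImage::imageData(rot), c(2, 1, 3)))
}

apply_variant <- function(img, variant, suite) {
  switch(variant,
    original  = img,
    hflip     = img[, rev(seq_len(dim(img)[2])), , drop = FALSE],
    rot_plus  = rotate_image(img, suite$rotation_deg),
    rot_minus = rotate_image(img, -suite$rotation_deg),
    bright_up = clip01(img * (1 + suite$brightness_delta)),
    ff_stop("unknown augmentation variant: ", variant,
            class = "ff_argument_error"))
}

#' Materialize the fixed augmentation suite over training images
#'
#' Emits exactly `length(suite$fixed_variants)` images per input image
#' (the original included), each tagged with its variant. Refuses input
#' that is already augmented, so augmentation can never be applied twice
#' nor to validation/test images by construction.
#'
#' @param samples list of `image_sample`, all with `augtag == "original"`.
#' @param suite an [aug_suite()].
#' @return list of `image_sample`, 5 per input.
#' @export
augment_training_images <- function(samples, suite = aug_suite()) {
  if (length(samples) == 0) return(list())
  tags <- vapply(samples, function(s) s$augtag, character(1))
  if (any(tags != "original"))
    ff_stop("input contains already-augmented images (no double augmentation)",
            class = "ff_validation_error")
  out <- vector("list", length(samples) * length(suite$fixed_variants))
  k <- 0L
  for (s in samples) {
    for (v in suite$fixed_variants) {
      k <- k + 1L
      out[[k]] <- image_sample(s$animal_id, s$view, v,
                               apply_variant(s$image, v, suite))
    }
  }
  out
}

# one stochastic draw of the on-the-fly training augmentation
augment_stochastic <- function(img, suite) {
  if (stats::runif(1) < suite$flip_prob)
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  ang <- stats::runif(1, -suite$rotation_deg, suite$rotation_deg)
  img <- rotate_image(img, ang)
  clip01(img * (1 + stats::runif(1, -suite$brightness_delta,
                                 suite$brightness_delta)))
}

# ---- leakage verification --------------------------------------------------

#' Verify animal-level leakage constraints
#'
#' Checks that (1) no animal has images in more than one partition and
#' (2) no augmented image sits outside the training partition.
#'
#' @param split a `split_manifest`.
#' @param images either a list of `image_sample`s each carrying a
#'   `partition` field, or a data frame with columns `animal_id`, `view`,
#'   `augtag`, `partition`.
#' @return a `leak_report`: data frame `(animal_id, type, detail)` with one
#'   row per violation (`type` is `cross_partition` or `augmentation_leak`);
#'   zero rows on clean data.
#' @export
verify_no_leakage <- function(split, images) {
  if (is.data.frame(images)) {
    man <- images
  } else {
    man <- do.call(rbind, lapply(images, function(s) {
      data.frame(animal_id = s$animal_id, view = s$view, augtag = s$augtag,
                 partition = s$partition %||%
                   NA_character_, stringsAsFactors = FALSE)
    }))
  }
  unknown <- setdiff(man$animal_id, split$animal_id)
  if (length(unknown) > 0)
    ff_stop("images reference animals absent from the split manifest: ",
            paste(utils::head(unknown, 3), collapse = ", "),
            class = "ff_validation_error")

  report <- data.frame(animal_id = character(0), type = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  parts_by_animal <- split(man$partition, man$animal_id)
  for (id in names(parts_by_animal)) {
    parts <- unique(parts_by_animal[[id]])
    if (length(parts) > 1)
      report <- rbind(report, data.frame(
        animal_id = id, type = "cross_partition",
        detail = paste(sort(parts), collapse = "+"),
        stringsAsFactors = FALSE))
  }
  aug_leak <- man$augtag != "original" & man$partition != "train"
  for (i in which(aug_leak))
    report <- rbind(report, data.frame(
      animal_id = man$animal_id[i], type = "augmentation_leak",
      detail = paste0(man$augtag[i], " in ", man$partition[i]),
      stringsAsFactors = FALSE))
  structure(report, class = c("leak_report", "data.frame"))
}

#' @export
print.leak_report <- function(x, ...) {
  if (nrow(x) == 0) cat("<leak_report> clean: 0 violations\n")
  else {
    cat(sprintf("<leak_report> %d violation(s)\n", nrow(x)))
    NextMethod()
  }
  invisible(x)
}

# ---- dataset assembly ------------------------------------------------------

#' Assemble a partitioned, augmented image dataset from a flock
#'
#' Renders both views of every animal, splits at the animal level, applies
#' the fixed augmentation suite to training images only, and returns the
#' samples together with an image manifest suitable for
#' [verify_no_leakage()].
#'
#' @param flock a `flock` data frame.
#' @param split a `split_manifest` over the flock's animals (default: a
#'   70/15/15 split with the given seed).
#' @param cfg a [render_config()].
#' @param suite an [aug_suite()]; `NULL` skips augmentation.
#' @param seed render seed.
#' @return list with `samples` (list of `image_sample` carrying a
#'   `partition` field), `manifest` (data frame `animal_id`, `view`,
#'   `augtag`, `partition`), and `split`.
#' @export
assemble_dataset <- function(flock, split = NULL, cfg = render_config(),
                             suite = aug_suite(), seed = 42L) {
  if (is.null(split))
    split <- partition_animals(flock$animal_id, seed = seed)
  part_of <- stats::setNames(split$partition, split$animal_id)
  originals <- render_flock(flock, cfg, seed)
  train_orig <- Filter(function(s) part_of[[s$animal_id]] == "train", originals)
  rest <- Filter(function(s) part_of[[s$animal_id]] != "train", originals)
  train_aug <- if (is.null(suite)) train_orig
               else augment_training_images(train_orig, suite)
  samples <- c(train_aug, rest)
  samples <- lapply(samples, function(s) {
    s$partition <- part_of[[s$animal_id]]
    s
  })
  manifest <- do.call(rbind, lapply(samples, function(s)
    data.frame(animal_id = s$animal_id, view = s$view, augtag = s$augtag,
               partition = s$partition, stringsAsFactors = FALSE)))
  list(samples = samples, manifest = manifest, split = split)
}

# ---- manifest CSV round trips ---------------------------------------------

#' Write / read split and fold manifests as CSV
#'
#' Round trips are field-identical; duplicated animal rows are rejected
#' with the offending line number.
#'
#' @param manifest a `split_manifest` or `fold_manifest`.
#' @param path CSV path.
#' @export
write_split_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  df$r_train <- attr(manifest, "ratios")[1]
  df$r_val <- attr(manifest, "ratios")[2]
  df$r_test <- attr(manifest, "ratios")[3]
  df$seed <- attr(manifest, "seed")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

check_manifest_ids <- function(df, path) {
  dup <- which(duplicated(df$animal_id))
  if (length(dup) > 0)
    ff_stop("duplicated animal row in ", path, " at line ", dup[1] + 1L,
            class = "ff_parse_error")
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("animal_id", "partition", "r_train", "r_val", "r_test", "seed")
  if (!all(need %in% names(df)))
    ff_stop("malformed split manifest ", path, class = "ff_parse_error")
  check_manifest_ids(df, path)
  structure(df[c("animal_id", "partition")],
            ratios = c(df$r_train[1], df$r_val[1], df$r_test[1]),
            seed = as.integer(df$seed[1]),
            class = c("split_manifest", "data.frame"))
}

#' @rdname write_split_manifest
#' @export
write_fold_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  df$k <- attr(manifest, "k")
  df$seed <- attr(manifest, "seed")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_fold_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("animal_id", "fold", "k", "seed")
  if (!all(need %in% names(df)))
    ff_stop("malformed fold manifest ", path, class = "ff_parse_error")
  check_manifest_ids(df, path)
  structure(df[c("animal_id", "fold")],
            k = as.integer(df$k[1]), seed = as.integer(df$seed[1]),
            class = c("fold_manifest", "data.frame"))
}
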