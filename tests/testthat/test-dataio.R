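# Partitioning, folds, augmentation and leakage checks.

test_that("partition counts follow the floor/ceil/remainder rule", {
  ids156 <- sprintf("E%03d", 1:156)
  sp <- partition_animals(ids156)
  counts <- table(sp$partition)
  expect_equal(as.integer(counts[c("train", "val", "test")]),
               as.integer(c(109, 24, 23)))

  sp10 <- partition_animals(sprintf("E%02d", 1:10), c(1, 0, 0))
  expect_equal(sum(sp10$partition == "train"), 10L)

  sp20 <- partition_animals(sprintf("E%02d", 1:20))
  expect_equal(as.integer(table(sp20$partition)[c("train", "val", "test")]),
               as.integer(c(14, 3, 3)))
})

test_that("changing the seed permutes membership but never counts", {
  ids <- sprintf("E%02d", 1:37)
  c1 <- partition_animals(ids, seed = 1)
  c2 <- partition_animals(ids, seed = 2)
  expect_equal(table(c1$partition), table(c2$partition))
  expect_false(identical(c1$animal_id[c1$partition == "train"],
                         c2$animal_id[c2$partition == "train"]))
  expect_setequal(c1$animal_id, ids)
})

test_that("partitioning rejects invalid input", {
  expect_error(partition_animals(c("a", "a", "b")),
               class = "ff_validation_error")
  expect_error(partition_animals(c("a", "b")), class = "ff_validation_error")
  expect_error(partition_animals(letters[1:9], c(0.5, 0.2, 0.2)),
               class = "ff_validation_error")
})

test_that("fold assignment balances fold sizes and is deterministic", {
  ids <- sprintf("E%03d", 1:156)
  fm <- assign_folds(ids, k = 10)
  sizes <- as.integer(table(fm$fold))
  expect_equal(sort(sizes), sort(c(rep(16L, 6), rep(15L, 4))))
  expect_identical(assign_folds(ids, k = 10), fm)

  fm1 <- assign_folds(letters[1:5], k = 5)
  expect_equal(as.integer(table(fm1$fold)), rep(1L, 5))
  expect_error(assign_folds(letters[1:3], k = 4),
               class = "ff_validation_error")
  expect_error(assign_folds(letters[1:3], k = 1), class = "ff_argument_error")
})

test_that("the fixed augmentation suite emits exactly five tagged variants", {
  fl <- cached_flock(400, seed = 5)
  cfg <- zero_noise_cfg()
  s <- render_animal(fl[1, ], "dorsal", cfg)
  out <- augment_training_images(list(s))
  expect_length(out, 5L)
  expect_equal(vapply(out, `[[`, character(1), "augtag"),
               c("original", "hflip", "rot_plus", "rot_minus", "bright_up"))
  # flip mirrors columns, brightness is multiplicative then clipped
  expect_equal(out[[2]]$image[, 64:1, ], s$image)
  expect_equal(out[[5]]$image[10, 40, ],
               pmin(1, s$image[10, 40, ] * 1.2))
  # rotations change the raster but keep its size
  expect_false(identical(out[[3]]$image, s$image))
  expect_equal(dim(out[[3]]$image), dim(s$image))
  expect_false(identical(out[[3]]$image, out[[4]]$image))

  # one animal x two views -> 10 images
  both <- augment_training_images(list(
    render_animal(fl[1, ], "dorsal", cfg),
    render_animal(fl[1, ], "lateral", cfg)))
  expect_length(both, 10L)

  expect_identical(augment_training_images(list()), list())
  expect_error(augment_training_images(out), class = "ff_validation_error")
})

test_that("leakage verification flags constructed violations only", {
  ids <- sprintf("E%02d", 1:12)
  sp <- partition_animals(ids, seed = 2)
  man <- merge(
    expand.grid(animal_id = ids, view = c("dorsal", "lateral"),
                stringsAsFactors = FALSE),
    as.data.frame(sp), by = "animal_id")
  man$augtag <- "original"
  clean <- verify_no_leakage(sp, man)
  expect_equal(nrow(clean), 0L)

  # one dorsal image moved from train to test -> 1 cross-partition violation
  tr <- which(man$partition == "train" & man$view == "dorsal")[1]
  moved <- man; moved$partition[tr] <- "test"
  rep1 <- verify_no_leakage(sp, moved)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$type, "cross_partition")
  expect_equal(rep1$animal_id, man$animal_id[tr])

  # a flipped image placed in val -> 1 augmentation-leak violation
  va <- which(man$partition == "val")[1]
  leaked <- rbind(man, data.frame(animal_id = man$animal_id[va],
                                  view = "dorsal", partition = "val",
                                  augtag = "hflip"))
  rep2 <- verify_no_leakage(sp, leaked)
  expect_equal(nrow(rep2), 1L)
  expect_equal(rep2$type, "augmentation_leak")

  bad <- man; bad$animal_id[1] <- "ghost"
  expect_error(verify_no_leakage(sp, bad), class = "ff_validation_error")
})

test_that("assembled datasets are leakage-free with correct multiplicities", {
  fl <- cached_flock(24, seed = 9)
  ds <- assemble_dataset(fl, cfg = zero_noise_cfg(), seed = 9)
  expect_equal(nrow(verify_no_leakage(ds$split, ds$manifest)), 0L)
  counts <- table(ds$manifest$partition)
  n_train <- sum(ds$split$partition == "train")
  expect_equal(unname(counts[["train"]]), n_train * 2L * 5L)
  expect_equal(unname(counts[["val"]]),
               sum(ds$split$partition == "val") * 2L)
  expect_equal(unname(counts[["test"]]),
               sum(ds$split$partition == "test") * 2L)
})

test_that("manifest CSV round trips are identical and reject duplicates", {
  ids <- sprintf("E%02d", 1:17)
  sp <- partition_animals(ids, seed = 4)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(sp, p1)
  expect_equal(read_split_manifest(p1), sp, ignore_attr = FALSE)

  fm <- assign_folds(ids, k = 10, seed = 4)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_fold_manifest(fm, p2)
  expect_equal(read_fold_manifest(p2), fm, ignore_attr = FALSE)

  df <- utils::read.csv(p1)
  utils::write.csv(rbind(df, df[3, ]), p1, row.names = FALSE)
  err <- tryCatch(read_split_manifest(p1), error = function(e) e)
  expect_s3_class(err, "ff_parse_error")
  expect_match(conditionMessage(err), "line")
})
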