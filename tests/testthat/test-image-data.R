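test_that("the loader reads a class-per-directory tree and normalizes to [0, 1]", {
  root <- withr::local_tempdir()
  for (cls in c("NORMAL", "PNEUMONIA")) {
    dir.create(file.path(root, "train", cls), recursive = TRUE)
    for (i in 1:2) {
      m <- matrix(stats::runif(64), 8, 8)
      if (cls == "NORMAL" && i == 1) m <- matrix(1, 8, 8)  # all-white probe
      png::writePNG(m, file.path(root, "train", cls, sprintf("i%d.png", i)))
    }
  }
  sets <- suppressMessages(load_dataset(root, target_size = c(8, 8)))
  expect_named(sets, "train")
  expect_length(sets$train$images, 4)
  expect_identical(sets$train$labels, c(0L, 0L, 1L, 1L))
  # the all-white 8-bit image scales to exactly 1.0 everywhere
  expect_true(all(sets$train$images[[1]] == 1.0))
  rng <- range(unlist(sets$train$images))
  expect_true(rng[1] >= 0 && rng[2] <= 1)
})

test_that("an empty class directory is an error naming the directory", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "train", "NORMAL"), recursive = TRUE)
  dir.create(file.path(root, "train", "PNEUMONIA"), recursive = TRUE)
  png::writePNG(matrix(0.5, 4, 4), file.path(root, "train", "NORMAL", "a.png"))
  expect_error(suppressMessages(load_dataset(root, c(4, 4))),
               "empty class directory.*PNEUMONIA")
})

test_that("unreadable files are skipped with a warning", {
  root <- withr::local_tempdir()
  for (cls in c("NORMAL", "PNEUMONIA")) {
    dir.create(file.path(root, "train", cls), recursive = TRUE)
    png::writePNG(matrix(0.5, 4, 4), file.path(root, "train", cls, "ok.png"))
  }
  writeLines("not a png", file.path(root, "train", "NORMAL", "broken.png"))
  expect_warning(sets <- suppressMessages(load_dataset(root, c(4, 4))),
                 "skipping unreadable")
  expect_length(sets$train$images, 2)
})

test_that("the canonical 5856-image pool splits into 4192/624/1040", {
  # balanced two-class pool of 5856 tiny images
  imgs <- replicate(5856, matrix(0.5, 2, 2), simplify = FALSE)
  labels <- rep(0:1, each = 2928)
  pool <- labeled_image_set(imgs, labels, source = "synthetic")
  sp <- stratified_split(pool, c(4192, 624, 1040) / 5856, seed = 1)
  expect_identical(vapply(sp, function(s) length(s$images), integer(1)),
                   c(train = 4192L, test = 624L, val = 1040L))
  # disjoint and exhaustive by count; balance preserved exactly
  expect_identical(sum(lengths(lapply(sp, `[[`, "images"))), 5856L)
  for (s in sp) expect_identical(sum(s$labels == 0L), length(s$labels) %/% 2L)
})

test_that("stratified splitting preserves class balance within one image", {
  imgs <- replicate(1000, matrix(0, 2, 2), simplify = FALSE)
  pool <- labeled_image_set(imgs, rep(0:1, each = 500))
  sp <- stratified_split(pool, c(0.8, 0.1, 0.1), seed = 2)
  for (s in sp)
    expect_lte(abs(sum(s$labels == 0L) - sum(s$labels == 1L)), 1L)
  expect_identical(length(sp$train$images), 800L)
  # degenerate fractions: everything in train
  sp1 <- stratified_split(pool, c(1, 0, 0), seed = 3)
  expect_identical(length(sp1$train$images), 1000L)
  expect_identical(length(sp1$test$images), 0L)
  expect_error(stratified_split(pool, c(0.5, 0.4, 0.2), seed = 1), "sum to 1")
})

test_that("augmentation unions originals with transformed copies", {
  set.seed(4)
  imgs <- replicate(6, matrix(stats::runif(256), 16, 16), simplify = FALSE)
  s <- labeled_image_set(imgs, rep(0:1, 3))
  a0 <- augment(s, augment_spec(), multiplier = 0)
  expect_identical(a0, s)
  a1 <- augment(s, augment_spec(), multiplier = 1, seed = 9)
  expect_length(a1$images, 12)
  expect_identical(a1$images[1:6], s$images)
  expect_identical(a1$labels, c(s$labels, s$labels))
  rng <- range(unlist(a1$images))
  expect_true(rng[1] >= 0 && rng[2] <= 1)
  # reproducible under the seed
  a2 <- augment(s, augment_spec(), multiplier = 1, seed = 9)
  expect_identical(a1, a2)
})

test_that("zeroed ranges reproduce the originals pixel for pixel", {
  set.seed(5)
  imgs <- replicate(4, matrix(stats::runif(64), 8, 8), simplify = FALSE)
  s <- labeled_image_set(imgs, c(0L, 0L, 1L, 1L))
  ident <- augment_spec(rotation_deg = 0, zoom_frac = 0, shift_frac = 0,
                        hflip_prob = 0)
  a <- augment(s, ident, multiplier = 1, seed = 1)
  expect_identical(a$images[5:8], imgs)
})

test_that("individual transforms behave geometrically", {
  m <- matrix(0, 9, 9); m[5, 7] <- 1
  s <- labeled_image_set(list(m), 1L)
  # pure horizontal flip mirrors columns
  flip_only <- augment_spec(0, 0, 0, hflip_prob = 1)
  a <- augment(s, flip_only, 1, seed = 1)
  expect_identical(a$images[[2]], m[, 9:1])
})
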