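# Synthetic two-class grayscale image generator.
#
# Emulates the one statistical property the classification task relies on:
# the positive ("pneumonia-like") class carries localized bright structure
# — soft elliptical opacity blobs — on top of the same smooth background
# and noise as the negative class.  Anatomical realism is explicitly not
# attempted; separability is a tunable knob (the blob intensity lift), so
# tests can certify task difficulty independently of any learned model.

#' Specification of a synthetic two-class image set
#'
#' @param n_per_class Images per class.
#' @param image_size `c(height, width)` in pixels.
#' @param background_knots Side length of the coarse random grid that is
#'   bilinearly upsampled into the smooth low-frequency background field.
#' @param background_range Intensity range `c(lo, hi)` of the background.
#' @param lesion_count_range Integer range `c(min, max)` of blobs per
#'   positive image.
#' @param lesion_radius_range Blob radius range as a fraction of the image
#'   width, e.g. `c(0.08, 0.2)`.
#' @param intensity_lift Peak added brightness of a blob in \[0, 1\]; 0
#'   makes the two classes distributionally identical (a chance-level
#'   task).
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = 200L,
                       image_size = c(32L, 32L),
                       background_knots = 4L,
                       background_range = c(0.25, 0.45),
                       lesion_count_range = c(1L, 3L),
                       lesion_radius_range = c(0.1, 0.22),
                       intensity_lift = 0.5,
                       noise_sd = 0.05,
                       seed = 1L) {
  if (intensity_lift < 0 || intensity_lift > 1)
    stop("intensity_lift must lie in [0, 1]", call. = FALSE)
  if (max(lesion_radius_range) >= 0.5)
    stop("lesion radius must be smaller than half the image", call. = FALSE)
  if (n_per_class < 0) stop("n_per_class must be >= 0", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 background_knots = as.integer(background_knots),
                 background_range = background_range,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = lesion_radius_range,
                 intensity_lift = intensity_lift,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Smooth low-frequency background: coarse uniform grid, bilinear upsample.
smooth_background <- function(h, w, knots, rng) {
  coarse <- matrix(stats::runif(knots^2, rng[1], rng[2]), knots, knots)
  up <- EBImage::resize(EBImage::Image(t(coarse)), w = w, h = h)
  t(EBImage::imageData(up))
}

# Add one soft elliptical Gaussian blob centered at (cy, cx).
add_blob <- function(m, cy, cx, ry, rx, lift, theta) {
  h <- nrow(m); w <- ncol(m)
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  m + lift * exp(-0.5 * ((u / rx)^2 + (v / ry)^2))
}

#' Generate a synthetic two-class image set
#'
#' Class 0 images are a smooth background plus Gaussian noise; class 1
#' images additionally carry 1-k soft elliptical bright blobs with the
#' configured intensity lift.  Classes are exactly balanced and all values
#' are clipped to \[0, 1\].  Fully deterministic given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @param split Split tag for the returned set.
#' @return A [labeled_image_set()] with `source = "synthetic"`.
#' @export
#' @examples
#' s <- generate_images(synth_spec(n_per_class = 10, seed = 7))
#' table(s$labels)
generate_images <- function(spec, split = "train") {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- spec$n_per_class
  images <- vector("list", 2L * n)
  labels <- integer(2L * n)
  for (i in seq_len(2L * n)) {
    cls <- as.integer(i > n)
    m <- smooth_background(h, w, spec$background_knots, spec$background_range)
    if (cls == 1L) {
      k <- sample(seq.int(spec$lesion_count_range[1], spec$lesion_count_range[2]), 1L)
      for (b in seq_len(k)) {
        r <- stats::runif(1, spec$lesion_radius_range[1],
                          spec$lesion_radius_range[2]) * w
        aspect <- stats::runif(1, 0.6, 1.4)
        cy <- stats::runif(1, r, h - r)
        cx <- stats::runif(1, r, w - r)
        m <- add_blob(m, cy, cx, r * aspect, r / aspect,
                      spec$intensity_lift, stats::runif(1, 0, pi))
      }
    }
    m <- m + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
    images[[i]] <- pmin(pmax(m, 0), 1)
    labels[i] <- cls
  }
  labeled_image_set(images, labels, split = split, source = "synthetic")
}

#' Write a labeled image set as a class-per-directory PNG tree
#'
#' Emits the exact `root/{split}/{NORMAL,PNEUMONIA}/*.png` layout consumed
#' by [load_dataset()], as 8-bit grayscale PNGs.  Class directories are
#' created even when empty.
#'
#' @param sets A single [labeled_image_set()] or a named list of them
#'   (names or `$split` tags give the split directories).
#' @param root_dir Output root (created if missing).
#' @return `root_dir`, invisibly.
#' @export
write_dataset_tree <- function(sets, root_dir) {
  if (inherits(sets, "labeled_image_set")) sets <- list(sets)
  dir.create(root_dir, recursive = TRUE, showWarnings = FALSE)
  for (set in sets) {
    for (cls in names(CLASS_DIRS))
      dir.create(file.path(root_dir, set$split, cls), recursive = TRUE,
                 showWarnings = FALSE)
    for (i in seq_along(set$images)) {
      cls <- names(CLASS_DIRS)[CLASS_DIRS == set$labels[i]]
      path <- file.path(root_dir, set$split, cls, sprintf("img_%05d.png", i))
      png::writePNG(set$images[[i]], path)
    }
  }
  invisible(root_dir)
}

#' Oracle pixel-mean threshold classifier
#'
#' A brute-force reference classifier independent of any neural network:
#' each image is reduced to its mean intensity, the threshold (and
#' direction) with the best training accuracy is found by sweeping all
#' midpoints between sorted training means, and the fitted rule is scored
#' on the test set.  Used to certify the separability of a synthetic task.
#'
#' @param train,test [labeled_image_set()]s.
#' @return A list with `threshold`, `direction` (+1 means class 1 has the
#'   larger mean), `train_accuracy`, `test_accuracy`.
#' @export
oracle_threshold_classifier <- function(train, test) {
  tr_means <- vapply(train$images, mean, numeric(1))
  te_means <- vapply(test$images, mean, numeric(1))
  ms <- sort(unique(tr_means))
  cuts <- if (length(ms) > 1) (ms[-1] + ms[-length(ms)]) / 2 else ms
  cuts <- c(min(ms) - 1e-9, cuts, max(ms) + 1e-9)
  best <- list(acc = -1)
  for (cut in cuts) for (dir in c(1, -1)) {
    pred <- as.integer(dir * tr_means > dir * cut)
    acc <- mean(pred == train$labels)
    if (acc > best$acc) best <- list(acc = acc, cut = cut, dir = dir)
  }
  pred_te <- as.integer(best$dir * te_means > best$dir * best$cut)
  list(threshold = best$cut, direction = best$dir,
       train_accuracy = best$acc,
       test_accuracy = mean(pred_te == test$labels))
}
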