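# Class-per-directory image datasets: loading, normalization, stratified
# splitting and the rotation/zoom/shift/flip augmentation set.

CLASS_DIRS <- c(NORMAL = 0L, PNEUMONIA = 1L)

#' A labeled set of grayscale images
#'
#' @param images List of numeric matrices (height x width) with values in
#'   \[0, 1\].
#' @param labels Integer 0/1 vector (0 = normal, 1 = pneumonia-like), one
#'   per image.
#' @param split One of `"train"`, `"test"`, `"val"`.
#' @param source `"loaded"` or `"synthetic"`.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, split = "train", source = "loaded") {
  if (length(images) != length(labels))
    stop("images and labels must have equal length", call. = FALSE)
  rng <- range(c(0, 1, unlist(lapply(images, range), use.names = FALSE)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  structure(list(images = images, labels = as.integer(labels),
                 split = match.arg(split, c("train", "test", "val")),
                 source = match.arg(source, c("loaded", "synthetic"))),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("<labeled_image_set> %s/%s: %d images (%d normal, %d pneumonia-like)\n",
              x$split, x$source, length(x$images),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

# Read one image file to a grayscale [0,1] matrix, resized to target_size.
read_gray_image <- function(path, target_size) {
  img <- EBImage::readImage(path)
  if (length(dim(img)) == 3L) img <- EBImage::channel(img, "gray")
  if (!is.null(target_size))
    img <- EBImage::resize(img, w = target_size[2], h = target_size[1])
  m <- t(EBImage::imageData(img))  # EBImage stores (x, y); we use (row, col)
  pmin(pmax(m, 0), 1)
}

#' Load a class-per-directory image dataset
#'
#' Expects the layout `root/{train,test,val}/{NORMAL,PNEUMONIA}/*.{png,jpg,jpeg}`.
#' Images are decoded, converted to a single grayscale channel, resized
#' bilinearly to `target_size` and scaled to \[0, 1\].  Unreadable files are
#' skipped with a warning; an empty class directory is an error.
#'
#' @param root_dir Dataset root.
#' @param target_size `c(height, width)` to resize to, or `NULL` to keep
#'   native resolutions.
#' @return A named list of [labeled_image_set()]s, one per split present.
#' @export
load_dataset <- function(root_dir, target_size = c(64, 64)) {
  if (!dir.exists(root_dir)) stop(sprintf("no such directory: %s", root_dir),
                                  call. = FALSE)
  splits <- intersect(c("train", "test", "val"), list.dirs(root_dir,
                      full.names = FALSE, recursive = FALSE))
  if (!length(splits))
    stop("root contains none of train/, test/, val/", call. = FALSE)
  out <- list()
  for (sp in splits) {
    images <- list(); labels <- integer(0); skipped <- 0L
    for (cls in names(CLASS_DIRS)) {
      cdir <- file.path(root_dir, sp, cls)
      if (!dir.exists(cdir)) next
      files <- list.files(cdir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                          full.names = TRUE)
      if (!length(files))
        stop(sprintf("empty class directory: %s", cdir), call. = FALSE)
      for (f in sort(files)) {
        m <- tryCatch(read_gray_image(f, target_size), error = function(e) NULL)
        if (is.null(m)) {
          warning(sprintf("skipping unreadable image: %s", f), call. = FALSE)
          skipped <- skipped + 1L
          next
        }
        images[[length(images) + 1L]] <- m
        labels <- c(labels, CLASS_DIRS[[cls]])
      }
    }
    message(sprintf("%s: %d images loaded (%d normal, %d pneumonia), %d skipped",
                    sp, length(images), sum(labels == 0L), sum(labels == 1L),
                    skipped))
    out[[sp]] <- labeled_image_set(images, labels, split = sp)
  }
  out
}

#' Stratified train/test/val split
#'
#' Shuffles each class with the given seed and allocates it to the three
#' splits by largest-remainder rounding, so per-class proportions are
#' preserved within one image and the splits are disjoint and exhaustive.
#'
#' @param pool A [labeled_image_set()].
#' @param fractions Numeric length-3 vector `(train, test, val)` summing to
#'   1 (tolerance 1e-9).
#' @param seed Integer seed for the shuffle.
#' @return A named list of three `labeled_image_set`s: `train`, `test`,
#'   `val`.
#' @export
#' @examples
#' # the canonical 5856-image layout: 4192 train, 624 test, 1040 val
#' # stratified_split(pool, c(4192, 624, 1040) / 5856, seed = 1)
stratified_split <- function(pool, fractions, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  set.seed(seed)
  idx_by_split <- list(integer(0), integer(0), integer(0))
  for (cls in unique(pool$labels)) {
    ci <- which(pool$labels == cls)
    if (length(ci) < sum(fractions > 0))
      stop(sprintf("class %d has %d images, fewer than the number of splits",
                   cls, length(ci)), call. = FALSE)
    ci <- ci[sample.int(length(ci))]
    alloc <- largest_remainder(length(ci) * fractions)
    stops <- cumsum(alloc)
    starts <- c(1L, stops[-length(stops)] + 1L)
    for (s in 1:3) if (alloc[s] > 0)
      idx_by_split[[s]] <- c(idx_by_split[[s]], ci[starts[s]:stops[s]])
  }
  names(idx_by_split) <- c("train", "test", "val")
  out <- lapply(c("train", "test", "val"), function(sp) {
    ii <- idx_by_split[[sp]]
    labeled_image_set(pool$images[ii], pool$labels[ii], split = sp,
                      source = pool$source)
  })
  names(out) <- c("train", "test", "val")
  out
}

# Integer allocation with the given (possibly fractional) targets summing
# to an integer: floor everything, hand out the remainder by largest
# fractional part (ties to the earlier split).
largest_remainder <- function(targets) {
  fl <- floor(targets + 1e-9)
  rem <- round(sum(targets)) - sum(fl)
  frac <- targets - fl
  add <- integer(length(targets))
  if (rem > 0) {
    ord <- order(-frac, seq_along(frac))
    add[ord[seq_len(rem)]] <- 1L
  }
  as.integer(fl + add)
}

#' Augmentation parameter set
#'
#' Ranges follow the standard radiograph recipe: planar rotation up to ±20
#' degrees, ±10% zoom, shifts up to ±10% of each dimension, and horizontal
#' flips with probability 0.5.
#'
#' @param rotation_deg Max absolute rotation angle in degrees.
#' @param zoom_frac Max absolute deviation of the scale factor from 1
#'   (0.1 means scale in \[0.9, 1.1\]).
#' @param shift_frac Max absolute shift as a fraction of each dimension.
#' @param hflip_prob Probability of a horizontal flip.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(rotation_deg = 20, zoom_frac = 0.1, shift_frac = 0.1,
                         hflip_prob = 0.5) {
  stopifnot(rotation_deg >= 0, zoom_frac >= 0, zoom_frac < 1, shift_frac >= 0,
            hflip_prob >= 0, hflip_prob <= 1)
  structure(list(rotation_deg = rotation_deg, zoom_frac = zoom_frac,
                 shift_frac = shift_frac, hflip_prob = hflip_prob),
            class = "augment_spec")
}

# Mean intensity of the 1-pixel image border, used to fill pixels that
# rotation or shifting moves out of frame.
edge_fill_value <- function(m) {
  mean(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
}

# Apply one random transform.  Operations whose sampled parameter is the
# exact identity (angle 0, scale 1, zero shift, no flip) are skipped so
# zeroed ranges reproduce the input bit for bit.
random_transform <- function(m, spec) {
  fill <- edge_fill_value(m)
  angle <- stats::runif(1, -spec$rotation_deg, spec$rotation_deg)
  scale <- stats::runif(1, 1 - spec$zoom_frac, 1 + spec$zoom_frac)
  dy <- round(stats::runif(1, -spec$shift_frac, spec$shift_frac) * nrow(m))
  dx <- round(stats::runif(1, -spec$shift_frac, spec$shift_frac) * ncol(m))
  flip <- stats::runif(1) < spec$hflip_prob
  if (angle != 0) {
    img <- EBImage::rotate(EBImage::Image(t(m)), angle,
                           output.dim = c(ncol(m), nrow(m)), bg.col = fill)
    m <- t(EBImage::imageData(img))
  }
  if (scale != 1) m <- center_zoom(m, scale, fill)
  if (dy != 0 || dx != 0) m <- shift_image(m, dy, dx, fill)
  if (flip) m <- m[, ncol(m):1, drop = FALSE]
  pmin(pmax(m, 0), 1)
}

# Center-anchored zoom: resize by `scale` then center-crop (scale > 1) or
# pad with the fill value (scale < 1) back to the original size.
center_zoom <- function(m, scale, fill) {
  h <- nrow(m); w <- ncol(m)
  nh <- max(1L, round(h * scale)); nw <- max(1L, round(w * scale))
  z <- EBImage::resize(EBImage::Image(t(m)), w = nw, h = nh)
  zm <- t(EBImage::imageData(z))
  out <- matrix(fill, h, w)
  if (scale >= 1) {
    r0 <- (nh - h) %/% 2L; c0 <- (nw - w) %/% 2L
    out <- zm[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w), drop = FALSE]
  } else {
    r0 <- (h - nh) %/% 2L; c0 <- (w - nw) %/% 2L
    out[(r0 + 1L):(r0 + nh), (c0 + 1L):(c0 + nw)] <- zm
  }
  out
}

# Integer-pixel shift with edge-value fill.
shift_image <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Augment a labeled image set
#'
#' Returns the union of the originals and `multiplier` transformed copies
#' of each image (so `multiplier = 1` doubles the set, `0` is the
#' identity).  Each copy samples an independent rotation, zoom, shift and
#' flip from `spec`; labels are inherited; intensities are clipped to
#' \[0, 1\].  Out-of-frame pixels are filled with the image's mean border
#' value.  Only the training split should be augmented by pipeline
#' drivers; this function itself is split-agnostic.
#'
#' @param set A [labeled_image_set()].
#' @param spec An [augment_spec()].
#' @param multiplier Nonnegative integer number of transformed copies per
#'   original.
#' @param seed Integer seed.
#' @return A `labeled_image_set` of `(multiplier + 1) * n` images, the
#'   first `n` identical to the originals.
#' @export
augment <- function(set, spec = augment_spec(), multiplier = 1L, seed = 1L) {
  stopifnot(multiplier >= 0)
  if (multiplier == 0) return(set)
  set.seed(seed)
  new_imgs <- list(); new_labs <- integer(0)
  for (rep_i in seq_len(multiplier)) {
    for (i in seq_along(set$images)) {
      new_imgs[[length(new_imgs) + 1L]] <- random_transform(set$images[[i]], spec)
      new_labs <- c(new_labs, set$labels[i])
    }
  }
  labeled_image_set(c(set$images, new_imgs), c(set$labels, new_labs),
                    split = set$split, source = set$source)
}
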