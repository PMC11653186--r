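# Translate chromosomes into backend-neutral architecture specifications.
#
# The evolved CNN follows a fixed scaffold: each chromosome layer becomes a
# same-padded Conv2D (stride 1, rectifier) followed by batch normalization,
# with a 2x2/stride-2 max pool after every second conv block; a flatten and
# a single sigmoid output unit close the network.  A 6-layer chromosome
# therefore yields 6 conv + 6 batch-norm + 3 max-pool descriptors.  The
# dense-head variant attaches flatten -> dropout -> dense stack -> sigmoid
# output to a frozen convolutional feature extractor.

#' Build the CNN architecture spec for a convolutional chromosome
#'
#' @param g A `conv_genome`.
#' @param input_shape Integer vector `c(height, width, channels)`.
#' @return An object of class `arch_spec`: list of layer descriptors, each
#'   a list with `kind` (one of conv, batch_norm, max_pool, flatten,
#'   dense, dropout, output) and kind-specific parameters, plus the
#'   propagated `output_shape` of each layer.
#' @export
#' @examples
#' cfg <- ga_config()
#' g <- conv_genome(list(c(224, 5), c(112, 5), c(208, 2),
#'                       c(135, 2), c(35, 2), c(104, 2)), cfg)
#' spec <- build_cnn_spec(g, c(64, 64, 1))
#' count_params(spec)
build_cnn_spec <- function(g, input_shape = c(64, 64, 1)) {
  validate_genome(g)
  stopifnot(length(input_shape) == 3)
  input_shape <- as.integer(input_shape)
  L <- nrow(g)
  n_pools <- L %/% 2L
  if (min(input_shape[1:2]) < 2^n_pools)
    stop(sprintf(
      "input %dx%d too small for %d max-pool layers (need >= %d pixels per side)",
      input_shape[1], input_shape[2], n_pools, 2^n_pools), call. = FALSE)
  h <- input_shape[1]; w <- input_shape[2]; c_in <- input_shape[3]
  layers <- list()
  for (i in seq_len(L)) {
    layers[[length(layers) + 1L]] <- list(
      kind = "conv", filters = unname(g[i, "filters"]),
      kernel = unname(g[i, "kernel"]), padding = "same", stride = 1L,
      activation = "relu", output_shape = c(h, w, unname(g[i, "filters"])))
    layers[[length(layers) + 1L]] <- list(
      kind = "batch_norm", channels = unname(g[i, "filters"]),
      output_shape = c(h, w, unname(g[i, "filters"])))
    if (i %% 2L == 0L) {
      h <- h %/% 2L; w <- w %/% 2L
      if (h < 1L || w < 1L)
        stop(sprintf("max pool after conv block %d collapses the spatial dims", i),
             call. = FALSE)
      layers[[length(layers) + 1L]] <- list(
        kind = "max_pool", pool = 2L, stride = 2L,
        output_shape = c(h, w, unname(g[i, "filters"])))
    }
    c_in <- unname(g[i, "filters"])
  }
  flat <- h * w * c_in
  layers[[length(layers) + 1L]] <- list(kind = "flatten", output_shape = flat)
  layers[[length(layers) + 1L]] <- list(
    kind = "output", units = 1L, activation = "sigmoid", output_shape = 1L)
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 frozen_backbone = FALSE),
            class = "arch_spec")
}

#' Build the dense-head spec for a frozen feature extractor
#'
#' Flatten -> dropout -> one dense layer per chromosome width (rectifier)
#' -> sigmoid output.  The spec is marked as attaching to a frozen
#' backbone: only the head's parameters are trainable.
#'
#' @param h A `dense_genome` of dense-layer widths.
#' @param feature_shape Shape `c(height, width, channels)` of the frozen
#'   extractor's feature maps (or a single integer feature dimension).
#' @param dropout_rate Dropout fraction after flattening (default 0.5).
#' @return An `arch_spec` with `frozen_backbone = TRUE`.
#' @export
build_head_spec <- function(h, feature_shape, dropout_rate = 0.5) {
  validate_genome(h)
  if (length(unclass(h)) < 1L) stop("head needs at least one dense layer", call. = FALSE)
  if (length(feature_shape) == 1L) feature_shape <- c(1L, 1L, feature_shape)
  feature_shape <- as.integer(feature_shape)
  flat <- as.integer(prod(feature_shape))
  layers <- list(
    list(kind = "flatten", output_shape = flat),
    list(kind = "dropout", rate = dropout_rate, output_shape = flat))
  for (wdt in as.integer(unclass(h))) {
    layers[[length(layers) + 1L]] <- list(
      kind = "dense", units = wdt, activation = "relu", output_shape = wdt)
  }
  layers[[length(layers) + 1L]] <- list(
    kind = "output", units = 1L, activation = "sigmoid", output_shape = 1L)
  structure(list(layers = layers, input_shape = as.integer(feature_shape),
                 frozen_backbone = TRUE),
            class = "arch_spec")
}

#' Count trainable parameters of an architecture spec
#'
#' Standard formulas: a same-padded conv layer has
#' `filters * (kernel^2 * in_channels) + filters` parameters, batch
#' normalization `2 * channels` (scale and shift), a dense layer
#' `in * out + out`.  Frozen-backbone layers are excluded (they never
#' appear in the spec; the spec's input is the extractor's output).
#'
#' @param spec An `arch_spec`.
#' @return Integer parameter count.
#' @export
count_params <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  c_in <- spec$input_shape[3]
  flat_in <- NA_integer_
  total <- 0
  for (ly in spec$layers) {
    total <- total + switch(ly$kind,
      conv = { p <- ly$filters * (ly$kernel^2 * c_in) + ly$filters
               c_in <- ly$filters; p },
      batch_norm = 2 * ly$channels,
      max_pool = 0,
      flatten = { flat_in <- ly$output_shape; 0 },
      dropout = 0,
      dense = { p <- flat_in * ly$units + ly$units; flat_in <- ly$units; p },
      output = { p <- flat_in * ly$units + ly$units; flat_in <- ly$units; p },
      stop(sprintf("unknown layer kind '%s'", ly$kind), call. = FALSE))
  }
  as.integer(total)
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> input %s%s\n",
              paste(x$input_shape, collapse = "x"),
              if (x$frozen_backbone) " (on frozen backbone)" else ""))
  for (ly in x$layers) cat(" ", layer_summary(ly), "\n")
  invisible(x)
}

layer_summary <- function(ly) {
  shp <- paste(ly$output_shape, collapse = "x")
  switch(ly$kind,
    conv = sprintf("conv %dx%d, %d filters, same, relu -> %s",
                   ly$kernel, ly$kernel, ly$filters, shp),
    batch_norm = sprintf("batch_norm (%d ch) -> %s", ly$channels, shp),
    max_pool = sprintf("max_pool 2x2 stride 2 -> %s", shp),
    flatten = sprintf("flatten -> %s", shp),
    dropout = sprintf("dropout %.2f -> %s", ly$rate, shp),
    dense = sprintf("dense %d, relu -> %s", ly$units, shp),
    output = sprintf("output %d, sigmoid -> %s", ly$units, shp))
}

#' One-line-per-layer text summary of a spec
#'
#' @param spec An `arch_spec`.
#' @return A character vector, one entry per layer.
#' @export
spec_summary <- function(spec) {
  vapply(spec$layers, layer_summary, character(1))
}

#' Serialize an architecture spec to JSON
#'
#' @param spec An `arch_spec`.
#' @return A JSON string.
#' @export
spec_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE)
}

#' Count layer kinds in a spec
#'
#' @param spec An `arch_spec`.
#' @return A named integer vector of counts per layer kind.
#' @export
spec_layer_counts <- function(spec) {
  kinds <- vapply(spec$layers, function(l) l$kind, character(1))
  table_k <- table(factor(kinds, levels = c("conv", "batch_norm", "max_pool",
                                            "flatten", "dropout", "dense", "output")))
  out <- as.integer(table_k); names(out) <- names(table_k)
  out
}
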