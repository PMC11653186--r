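# Shared fixtures: small configs, tiny genome spaces and dataset builders.

# A small chromosome space (342 points) that can be enumerated exhaustively:
# lengths 1-2, filter counts 1-6, kernel sizes 1-3.
tiny_space_config <- function(seed = 1, patience = 5, ...) {
  ga_config(max_layers = 2, max_filters = 6, max_filter_size = 3,
            population_size = 20, max_generations = 30, patience = patience,
            seed = seed, ...)
}

# Enumerate every genome in a tiny_space_config() space as encoded vectors.
enumerate_tiny_space <- function(cfg) {
  out <- list()
  for (f1 in 1:cfg$max_filters) for (k1 in 1:cfg$max_filter_size) {
    out[[length(out) + 1L]] <- c(f1, k1)
    for (f2 in 1:cfg$max_filters) for (k2 in 1:cfg$max_filter_size)
      out[[length(out) + 1L]] <- c(f1, k1, f2, k2)
  }
  out
}

# Balanced synthetic train/val/test sets at a given separability.
tiny_split_data <- function(n_per_class = 40, image_size = c(16, 16),
                            lift = 0.5, noise_sd = 0.05, seed = 1) {
  pool <- generate_images(synth_spec(n_per_class = n_per_class,
                                     image_size = image_size,
                                     intensity_lift = lift,
                                     noise_sd = noise_sd, seed = seed))
  stratified_split(pool, c(0.6, 0.2, 0.2), seed = seed)
}

# Independent per-layer parameter count for the evolved-CNN scaffold:
# same-padded conv + batch norm per chromosome layer, pool after every
# second block, flatten, one sigmoid output unit.
hand_count_params <- function(filters, kernels, input_shape) {
  h <- input_shape[1]; w <- input_shape[2]; c_in <- input_shape[3]
  total <- 0
  for (i in seq_along(filters)) {
    total <- total + filters[i] * (kernels[i]^2 * c_in) + filters[i]  # conv
    total <- total + 2 * filters[i]                                   # batch norm
    c_in <- filters[i]
    if (i %% 2 == 0) { h <- h %/% 2; w <- w %/% 2 }
  }
  total + (h * w * c_in) * 1 + 1                                      # output
}
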