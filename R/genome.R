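# Chromosome encodings and run configuration for the architecture search.
#
# A convolutional chromosome is an ordered list of layers, each layer a
# (filter_count, filter_size) pair of positive integers; its length (the
# number of convolutional layers) is itself evolvable.  A dense-head
# chromosome is a vector of dense-layer widths used when searching the
# classification head on top of a frozen feature extractor.

#' Genetic-algorithm run configuration
#'
#' Collects every control parameter of the evolutionary search: population
#' size, generation cap, chromosome bounds, operator rates, elitism,
#' plateau patience and the fitness variant.
#'
#' @param population_size Number of individuals per generation.
#' @param max_generations Hard cap on the number of generations.
#' @param max_layers Maximum number of convolutional layers (chromosome
#'   length); minimum is 1.
#' @param max_filters Upper bound (inclusive) on the per-layer filter count;
#'   lower bound is 1.
#' @param max_filter_size Upper bound (inclusive) on the square kernel size
#'   in pixels; lower bound is 1.
#' @param min_neurons,max_neurons Inclusive bounds on dense-head widths.
#' @param p_c Uniform-crossover probability: each child gene is copied from
#'   parent 1 with probability `p_c`, else from parent 2.
#' @param mutation_rate Per-gene probability of perturbation.  The default
#'   0.25 gives roughly one perturbed gene per child on the short (4-12
#'   gene) chromosomes this search uses, the usual one-mutation-per-
#'   chromosome heuristic.
#' @param mutation_delta Perturbation spec, a list with elements `family`
#'   (currently `"uniform_int"`) and `scale`: either a positive integer
#'   half-width d (the perturbation is drawn uniformly from
#'   {-d, ..., -1, 1, ..., d}) or the string `"auto"`, which sets d to
#'   ceiling(10% of the gene's range).
#' @param elitism_k Number of top individuals retained unchanged each
#'   generation.
#' @param patience Number of consecutive generations without strict
#'   improvement (beyond 1e-9) of the best fitness before the run stops.
#' @param seed Integer seed controlling every random draw of the run.
#' @param fitness_kind One of `"accuracy_pct"` (percentage of correct
#'   predictions, the default used during evolution), `"confusion"`
#'   (TP / (TP + FP + FN)) or `"surrogate"` (a user-supplied cheap
#'   deterministic fitness, no training).
#' @param structural_mutation If `TRUE`, mutation may additionally insert or
#'   delete one random layer with probability `mutation_rate` (off by
#'   default).
#' @param cost_weights Optional [cost_weights()] used for reporting the
#'   architecture cost of evolved genomes.
#'
#' @return An object of class `ga_config` (a validated list).
#' @export
#' @examples
#' cfg <- ga_config(population_size = 10, max_layers = 6)
#' g <- random_genome(cfg)
ga_config <- function(population_size = 20,
                      max_generations = 11,
                      max_layers = 6,
                      max_filters = 256,
                      max_filter_size = 7,
                      min_neurons = 200,
                      max_neurons = 600,
                      p_c = 0.5,
                      mutation_rate = 0.25,
                      mutation_delta = list(family = "uniform_int", scale = "auto"),
                      elitism_k = NULL,
                      patience = 3,
                      seed = 1L,
                      fitness_kind = c("accuracy_pct", "confusion", "surrogate"),
                      structural_mutation = FALSE,
                      cost_weights = NULL) {
  fitness_kind <- match.arg(fitness_kind)
  if (is.null(elitism_k)) elitism_k <- ceiling(population_size / 4)
  cfg <- list(
    population_size = as.integer(population_size),
    max_generations = as.integer(max_generations),
    max_layers = as.integer(max_layers),
    max_filters = as.integer(max_filters),
    max_filter_size = as.integer(max_filter_size),
    min_neurons = as.integer(min_neurons),
    max_neurons = as.integer(max_neurons),
    p_c = p_c,
    mutation_rate = mutation_rate,
    mutation_delta = mutation_delta,
    elitism_k = as.integer(elitism_k),
    patience = as.integer(patience),
    seed = as.integer(seed),
    fitness_kind = fitness_kind,
    structural_mutation = isTRUE(structural_mutation),
    cost_weights = cost_weights
  )
  class(cfg) <- "ga_config"
  validate_ga_config(cfg)
  cfg
}

validate_ga_config <- function(cfg) {
  stopifnot(inherits(cfg, "ga_config"))
  with(cfg, {
    if (population_size < 1L) stop("population_size must be >= 1", call. = FALSE)
    if (max_generations < 1L) stop("max_generations must be >= 1", call. = FALSE)
    if (max_layers < 1L) stop("max_layers must be >= 1", call. = FALSE)
    if (max_filters < 1L || max_filter_size < 1L)
      stop("filter bounds must be >= 1", call. = FALSE)
    if (min_neurons < 1L || max_neurons < min_neurons)
      stop("neuron bounds invalid: need 1 <= min_neurons <= max_neurons", call. = FALSE)
    if (p_c < 0 || p_c > 1) stop("p_c must lie in [0, 1]", call. = FALSE)
    if (mutation_rate < 0 || mutation_rate > 1)
      stop("mutation_rate must lie in [0, 1]", call. = FALSE)
    if (elitism_k < 1L || elitism_k > population_size)
      stop("elitism_k must lie in [1, population_size]", call. = FALSE)
    if (patience < 1L) stop("patience must be >= 1", call. = FALSE)
  })
  invisible(cfg)
}

#' Weights of the architecture cost
#'
#' Nonnegative weights on the number of layers (`alpha`), the total filter
#' count (`beta`) and the error rate (`gamma`) entering
#' [arch_cost()].
#'
#' @param alpha,beta,gamma Nonnegative finite reals.
#' @return An object of class `cost_weights`.
#' @export
cost_weights <- function(alpha = 0, beta = 0, gamma = 1) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(w)) || any(w < 0))
    stop("cost weights must be finite and >= 0", call. = FALSE)
  structure(as.list(w), class = "cost_weights")
}

#' Construct a convolutional chromosome
#'
#' @param layers A list of length-2 integer vectors `c(filter_count,
#'   filter_size)`, or a 2-column matrix (one row per layer).
#' @param config A [ga_config()] supplying the bounds.
#' @return An object of class `conv_genome`: a matrix with columns
#'   `filters` and `kernel`, one row per convolutional layer.
#' @export
#' @examples
#' cfg <- ga_config()
#' conv_genome(list(c(224, 5), c(112, 5), c(208, 2)), cfg)
conv_genome <- function(layers, config) {
  if (is.matrix(layers)) {
    m <- layers
  } else {
    m <- do.call(rbind, lapply(layers, function(l) as.integer(l[1:2])))
  }
  storage.mode(m) <- "integer"
  colnames(m) <- c("filters", "kernel")
  g <- structure(m, class = "conv_genome",
                 bounds = genome_bounds(config, "conv"))
  validate_genome(g)
  g
}

#' Construct a dense-head chromosome
#'
#' Widths of the dense layers appended to a frozen feature extractor.
#'
#' @param widths Positive integer vector of neurons per dense layer.
#' @param config A [ga_config()] supplying `min_neurons`/`max_neurons`.
#' @return An object of class `dense_genome`.
#' @export
dense_genome <- function(widths, config) {
  g <- structure(as.integer(widths), class = "dense_genome",
                 bounds = genome_bounds(config, "dense"))
  validate_genome(g)
  g
}

genome_bounds <- function(config, kind) {
  if (kind == "conv") {
    list(kind = "conv", max_layers = config$max_layers,
         max_filters = config$max_filters,
         max_filter_size = config$max_filter_size)
  } else {
    list(kind = "dense", min_neurons = config$min_neurons,
         max_neurons = config$max_neurons)
  }
}

#' @export
print.conv_genome <- function(x, ...) {
  cat(sprintf("<conv_genome: %d layer%s>\n", nrow(x), if (nrow(x) > 1) "s" else ""))
  cat(sprintf("  filters: %s\n", paste(x[, "filters"], collapse = ", ")))
  cat(sprintf("  kernels: %s\n", paste(x[, "kernel"], collapse = ", ")))
  invisible(x)
}

#' @export
print.dense_genome <- function(x, ...) {
  cat(sprintf("<dense_genome: widths %s>\n", paste(unclass(x), collapse = ", ")))
  invisible(x)
}

#' Validate a chromosome against its bounds
#'
#' @param g A `conv_genome` or `dense_genome`.
#' @return `g`, invisibly; errors if an invariant is violated.
#' @export
validate_genome <- function(g) {
  b <- attr(g, "bounds")
  if (is.null(b)) stop("genome carries no bounds", call. = FALSE)
  if (b$kind == "conv") {
    if (!is.matrix(g) || ncol(g) != 2L || nrow(g) < 1L)
      stop("conv genome must have at least one (filters, kernel) layer", call. = FALSE)
    if (nrow(g) > b$max_layers)
      stop(sprintf("genome has %d layers, max_layers is %d", nrow(g), b$max_layers),
           call. = FALSE)
    if (any(g[, "filters"] < 1L) || any(g[, "filters"] > b$max_filters))
      stop(sprintf("filter counts must lie in [1, %d]", b$max_filters), call. = FALSE)
    if (any(g[, "kernel"] < 1L) || any(g[, "kernel"] > b$max_filter_size))
      stop(sprintf("filter sizes must lie in [1, %d]", b$max_filter_size), call. = FALSE)
  } else {
    if (length(g) < 1L) stop("dense genome must have at least one width", call. = FALSE)
    if (any(g < b$min_neurons) || any(g > b$max_neurons))
      stop(sprintf("widths must lie in [%d, %d]", b$min_neurons, b$max_neurons),
           call. = FALSE)
  }
  invisible(g)
}

#' Draw a random convolutional chromosome
#'
#' Layer count uniform on `1:max_layers`; every filter count uniform on
#' `1:max_filters`; every kernel size uniform on `1:max_filter_size`.
#' Uses the current R random-number stream.
#'
#' @param config A [ga_config()].
#' @return A valid `conv_genome`.
#' @export
random_genome <- function(config) {
  validate_ga_config(config)
  L <- sample.int(config$max_layers, 1L)
  m <- cbind(filters = sample.int(config$max_filters, L, replace = TRUE),
             kernel = sample.int(config$max_filter_size, L, replace = TRUE))
  conv_genome(m, config)
}

#' Draw a random dense-head chromosome
#'
#' @param config A [ga_config()].
#' @param n_layers Number of dense layers (default 2).
#' @return A valid `dense_genome` with widths uniform on
#'   `min_neurons:max_neurons`.
#' @export
random_dense_genome <- function(config, n_layers = 2L) {
  widths <- sample(seq.int(config$min_neurons, config$max_neurons), n_layers,
                   replace = TRUE)
  dense_genome(widths, config)
}

#' Flatten a chromosome to an integer vector
#'
#' Conv genomes interleave (filter_count, filter_size) pairs, so a 6-layer
#' genome becomes a length-12 vector; dense genomes are already flat.
#' `decode_genome()` is the exact inverse and validates bounds.
#'
#' @param g A `conv_genome` or `dense_genome`.
#' @return An integer vector.
#' @export
#' @examples
#' cfg <- ga_config()
#' v <- encode_genome(conv_genome(list(c(8, 3)), cfg))  # c(8, 3)
#' identical(decode_genome(v, cfg), conv_genome(list(c(8, 3)), cfg))
encode_genome <- function(g) {
  if (inherits(g, "dense_genome")) return(as.integer(unclass(g)))
  as.integer(t(unclass(g)))
}

#' Rebuild a chromosome from its flat integer encoding
#'
#' @param v Integer vector of interleaved (filter_count, filter_size) pairs
#'   (for `kind = "conv"`; length must be even and >= 2) or dense widths.
#' @param config A [ga_config()].
#' @param kind `"conv"` or `"dense"`.
#' @return The decoded genome; errors name the first out-of-bounds index
#'   (1-based position in `v`).
#' @export
decode_genome <- function(v, config, kind = c("conv", "dense")) {
  kind <- match.arg(kind)
  v <- as.integer(v)
  if (kind == "dense") return(dense_genome(v, config))
  if (length(v) < 2L || length(v) %% 2L != 0L)
    stop("conv encoding must have even length >= 2 (count, size pairs)", call. = FALSE)
  counts <- v[seq(1L, length(v), by = 2L)]
  sizes <- v[seq(2L, length(v), by = 2L)]
  bad_count <- which(counts < 1L | counts > config$max_filters)
  if (length(bad_count))
    stop(sprintf("filter count out of bounds at encoding index %d (value %d)",
                 2L * bad_count[1] - 1L, counts[bad_count[1]]), call. = FALSE)
  bad_size <- which(sizes < 1L | sizes > config$max_filter_size)
  if (length(bad_size))
    stop(sprintf("filter size out of bounds at encoding index %d (value %d)",
                 2L * bad_size[1], sizes[bad_size[1]]), call. = FALSE)
  if (length(counts) > config$max_layers)
    stop(sprintf("encoding implies %d layers, max_layers is %d",
                 length(counts), config$max_layers), call. = FALSE)
  conv_genome(cbind(filters = counts, kernel = sizes), config)
}

# Half-width d of the additive mutation for one gene with range [lo, hi].
# "auto" -> ceiling of 10% of the range, never below 1.
delta_half_width <- function(mutation_delta, lo, hi) {
  scale <- mutation_delta$scale
  if (identical(scale, "auto")) max(1L, as.integer(ceiling(0.1 * (hi - lo))))
  else max(1L, as.integer(scale))
}

# Draw n perturbations from {-d,...,-1, 1,...,d}.
draw_delta <- function(n, d) {
  mag <- sample.int(d, n, replace = TRUE)
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  mag * sgn
}

#' Serialize a genome to JSON
#'
#' Conv genomes become a list of `[filters, kernel]` pairs, dense genomes a
#' flat width list — the representation used in run manifests.
#'
#' @param g A genome.
#' @return A JSON string.
#' @export
genome_to_json <- function(g) {
  if (inherits(g, "dense_genome")) {
    jsonlite::toJSON(list(kind = "dense", widths = as.integer(unclass(g))),
                     auto_unbox = TRUE)
  } else {
    pairs <- lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
    jsonlite::toJSON(list(kind = "conv", layers = pairs), auto_unbox = TRUE)
  }
}

#' Deserialize a genome from JSON
#'
#' @param txt JSON produced by [genome_to_json()].
#' @param config A [ga_config()] for bound validation.
#' @return The genome.
#' @export
genome_from_json <- function(txt, config) {
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (identical(x$kind, "dense")) {
    dense_genome(unlist(x$widths), config)
  } else {
    conv_genome(lapply(x$layers, unlist), config)
  }
}
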