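# Evolutionary loop: initialization, crossover (uniform and
# length-altering), bounded additive mutation, elitist survivor selection
# and plateau-based stopping.

#' Create an individual
#'
#' @param genome A genome object.
#' @param fitness Fitness value, or `NA` if not yet evaluated.
#' @param generation_born Generation index at which the genome appeared.
#' @return An object of class `individual`.
#' @export
new_individual <- function(genome, fitness = NA_real_, generation_born = 0L) {
  structure(list(genome = genome, fitness = fitness,
                 generation_born = as.integer(generation_born)),
            class = "individual")
}

#' Initialize a population of random genomes
#'
#' Draws exactly `config$population_size` random chromosomes (all
#' unevaluated) at generation 0 using the current RNG stream.
#'
#' @param config A [ga_config()].
#' @return An object of class `population`: a list with `individuals` and
#'   `generation`.
#' @export
initialize_population <- function(config) {
  validate_ga_config(config)
  inds <- replicate(config$population_size,
                    new_individual(random_genome(config)), simplify = FALSE)
  structure(list(individuals = inds, generation = 0L), class = "population")
}

#' Uniform crossover of two equal-length chromosomes
#'
#' Gene i of the child is copied from `p1` with probability `p_c`, else
#' from `p2`.  This operator never changes the chromosome length; parents
#' of unequal length must first go through [length_crossover()].
#'
#' @param p1,p2 Genomes of identical length and kind.
#' @param p_c Probability that a gene comes from `p1`.
#' @return A child genome.
#' @export
uniform_crossover <- function(p1, p2, p_c) {
  v1 <- encode_genome(p1); v2 <- encode_genome(p2)
  if (length(v1) != length(v2))
    stop("uniform_crossover requires equal-length parents; use length_crossover",
         call. = FALSE)
  take1 <- stats::runif(length(v1)) < p_c
  child <- ifelse(take1, v1, v2)
  rebuild_like(p1, child)
}

# Rebuild a genome of the same class/bounds as `template` from a flat vector.
rebuild_like <- function(template, v) {
  b <- attr(template, "bounds")
  if (inherits(template, "dense_genome")) {
    g <- structure(as.integer(v), class = "dense_genome", bounds = b)
  } else {
    m <- matrix(as.integer(v), ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("filters", "kernel")))
    g <- structure(m, class = "conv_genome", bounds = b)
  }
  validate_genome(g)
  g
}

#' Length-altering (structural) crossover
#'
#' The first crossover sub-operator: it changes the number of chromosome
#' columns, i.e. the number of convolutional layers.  The child length L is
#' drawn uniformly from `[min(L1, L2), max(L1, L2)]` (clamped to
#' `[1, max_layers]`); layer i of the child is copied from a uniformly
#' chosen parent that has a layer i.
#'
#' @param p1,p2 `conv_genome` parents, possibly of unequal length.
#' @param config A [ga_config()].
#' @return A child `conv_genome`.
#' @export
length_crossover <- function(p1, p2, config) {
  L1 <- genome_length(p1); L2 <- genome_length(p2)
  lo <- min(L1, L2); hi <- max(L1, L2)
  lo <- max(1L, lo); hi <- min(hi, config$max_layers)
  L <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
  rows <- lapply(seq_len(L), function(i) {
    has1 <- i <= L1; has2 <- i <= L2
    src <- if (has1 && has2) sample(1:2, 1L) else if (has1) 1L else 2L
    if (src == 1L) unclass(p1)[i, ] else unclass(p2)[i, ]
  })
  rebuild_like(p1, as.integer(t(do.call(rbind, rows))))
}

genome_length <- function(g) {
  if (inherits(g, "dense_genome")) length(unclass(g)) else nrow(unclass(g))
}

#' Bounded additive mutation
#'
#' Each gene is independently perturbed with probability `mutation_rate` by
#' an integer drawn uniformly from `{-d, ..., -1, 1, ..., d}` and then
#' clamped to its bounds (d is the half-width from the config's
#' `mutation_delta`; `"auto"` gives d = ceiling(10% of the gene's range)).
#' With `config$structural_mutation = TRUE`, one random layer is
#' additionally inserted or deleted with probability `mutation_rate`.
#'
#' @param g A genome.
#' @param config A [ga_config()].
#' @return The mutated genome (equal to `g` when nothing fires).
#' @export
mutate_genome <- function(g, config) {
  v <- encode_genome(g)
  if (inherits(g, "dense_genome")) {
    lo <- rep(config$min_neurons, length(v))
    hi <- rep(config$max_neurons, length(v))
  } else {
    lo <- rep(1L, length(v))
    hi <- rep(c(config$max_filters, config$max_filter_size),
              length.out = length(v))
  }
  fire <- stats::runif(length(v)) < config$mutation_rate
  if (any(fire)) {
    idx <- which(fire)
    deltas <- vapply(idx, function(i) {
      d <- delta_half_width(config$mutation_delta, lo[i], hi[i])
      draw_delta(1L, d)
    }, integer(1))
    v[idx] <- pmin(pmax(v[idx] + deltas, lo[idx]), hi[idx])
  }
  g2 <- rebuild_like(g, v)
  if (config$structural_mutation && inherits(g, "conv_genome") &&
      stats::runif(1) < config$mutation_rate) {
    g2 <- structural_mutate(g2, config)
  }
  g2
}

# Insert a random layer (if below max_layers) or delete one (if above 1);
# when both moves are legal, choose uniformly.
structural_mutate <- function(g, config) {
  L <- nrow(g)
  can_ins <- L < config$max_layers
  can_del <- L > 1L
  if (!can_ins && !can_del) return(g)
  ins <- if (can_ins && can_del) sample(c(TRUE, FALSE), 1L) else can_ins
  m <- unclass(g)
  if (ins) {
    at <- sample.int(L + 1L, 1L)
    newrow <- c(sample.int(config$max_filters, 1L),
                sample.int(config$max_filter_size, 1L))
    m <- rbind(m[seq_len(at - 1L), , drop = FALSE], newrow,
               m[seq_len(L)[seq_len(L) >= at], , drop = FALSE])
  } else {
    at <- sample.int(L, 1L)
    m <- m[-at, , drop = FALSE]
  }
  rownames(m) <- NULL
  rebuild_like(g, as.integer(t(m)))
}

#' Elitist survivor selection
#'
#' Returns exactly the `k` highest-fitness individuals.  Ties are broken by
#' earlier `generation_born`, then by the lexicographically smaller genome
#' encoding, so selection is a deterministic total order.
#'
#' @param population A `population` with every individual evaluated.
#' @param k Number of survivors, `1 <= k <=` population size.
#' @return A `population` of the `k` survivors (same generation index).
#' @export
select_survivors <- function(population, k) {
  inds <- population$individuals
  n <- length(inds)
  if (k < 1L || k > n) stop("k must lie in [1, population size]", call. = FALSE)
  fit <- vapply(inds, function(i) i$fitness, numeric(1))
  if (any(is.na(fit)))
    stop("select_survivors requires every individual to be evaluated", call. = FALSE)
  born <- vapply(inds, function(i) i$generation_born, integer(1))
  keys <- vapply(inds, function(i)
    paste(sprintf("%010d", encode_genome(i$genome)), collapse = ","), character(1))
  ord <- order(-fit, born, keys)
  structure(list(individuals = inds[ord[seq_len(k)]],
                 generation = population$generation),
            class = "population")
}

#' Run the evolutionary search
#'
#' Each generation: evaluate unevaluated genomes with `fitness_fn`, record
#' history, keep the `elitism_k` best unchanged and refill the population
#' with children (two parents drawn uniformly from the elite pool;
#' equal-length parents undergo uniform crossover, unequal-length parents
#' the length-altering crossover; every child is then mutated).  The run
#' stops at `max_generations` or once the best fitness has not improved by
#' more than 1e-9 for `patience` consecutive generations.  With
#' `elitism_k >= 1` the best fitness is non-decreasing across generations.
#'
#' @param config A [ga_config()]; `config$seed` seeds the run.
#' @param fitness_fn Function genome -> finite numeric fitness (higher is
#'   better).  An error raised by `fitness_fn` aborts the run with the
#'   offending generation and genome in the condition message.
#' @param genome_sampler Optional function(config) -> genome used for
#'   initialization (defaults to [random_genome()]; pass
#'   [random_dense_genome()] wrapped appropriately for head search).
#' @return A list with `best` (best-ever `individual`), `history` (a data
#'   frame with one row per generation: `generation`, `best_fitness`,
#'   `mean_fitness`, `best_genome_json`) and `stop_reason`
#'   (`"plateau"` or `"max_generations"`).
#' @export
#' @examples
#' cfg <- ga_config(population_size = 8, max_layers = 2, max_filters = 8,
#'                  max_filter_size = 3, max_generations = 10, seed = 7)
#' res <- evolve(cfg, function(g) -sum(abs(encode_genome(g) - c(4, 2, 6, 1))))
#' res$best$fitness
evolve <- function(config, fitness_fn, genome_sampler = random_genome) {
  validate_ga_config(config)
  set.seed(config$seed)
  inds <- replicate(config$population_size,
                    new_individual(genome_sampler(config)), simplify = FALSE)
  best_ever <- NULL
  stale <- 0L
  history <- vector("list", config$max_generations)
  stop_reason <- "max_generations"

  for (gen in seq_len(config$max_generations) - 1L) {
    inds <- lapply(inds, function(ind) {
      if (!is.na(ind$fitness)) return(ind)
      f <- tryCatch(fitness_fn(ind$genome), error = function(e)
        stop(sprintf("fitness evaluation failed at generation %d on genome %s: %s",
                     gen, genome_to_json(ind$genome), conditionMessage(e)),
             call. = FALSE))
      if (!is.finite(f)) stop("fitness_fn returned a non-finite value", call. = FALSE)
      ind$fitness <- f
      ind
    })
    pop <- structure(list(individuals = inds, generation = gen), class = "population")
    top <- select_survivors(pop, 1L)$individuals[[1]]
    improved <- is.null(best_ever) || top$fitness > best_ever$fitness + 1e-9
    if (improved) { best_ever <- top; stale <- 0L } else stale <- stale + 1L
    fits <- vapply(inds, function(i) i$fitness, numeric(1))
    history[[gen + 1L]] <- data.frame(
      generation = gen,
      best_fitness = best_ever$fitness,
      mean_fitness = mean(fits),
      best_genome_json = as.character(genome_to_json(best_ever$genome)),
      stringsAsFactors = FALSE)
    if (stale >= config$patience) { stop_reason <- "plateau"; break }
    if (gen == config$max_generations - 1L) break

    elite <- select_survivors(pop, config$elitism_k)$individuals
    n_children <- config$population_size - config$elitism_k
    children <- lapply(seq_len(n_children), function(j) {
      ps <- sample.int(length(elite), 2L, replace = length(elite) == 1L)
      p1 <- elite[[ps[1]]]$genome; p2 <- elite[[ps[2]]]$genome
      child <- if (genome_length(p1) == genome_length(p2))
        uniform_crossover(p1, p2, config$p_c)
      else
        length_crossover(p1, p2, config)
      new_individual(mutate_genome(child, config), generation_born = gen + 1L)
    })
    inds <- c(elite, children)
  }

  list(best = best_ever,
       history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
       stop_reason = stop_reason)
}

#' Surrogate fitness: negative L1 distance to a target genome
#'
#' A cheap, deterministic landscape with a unique global optimum at
#' `target` (fitness 0), used to exercise the search loop without any
#' model training.  Chromosomes of a different length are penalized by the
#' full gene range for each missing/extra layer, so the optimum length is
#' the target's.
#'
#' @param target A `conv_genome`.
#' @param config The [ga_config()] defining gene ranges.
#' @return A function genome -> numeric fitness (<= 0; 0 iff genome ==
#'   target).
#' @export
surrogate_fitness_l1 <- function(target, config) {
  tv <- encode_genome(target)
  per_layer_penalty <- (config$max_filters - 1L) + (config$max_filter_size - 1L)
  function(g) {
    v <- encode_genome(g)
    n <- min(length(v), length(tv))
    d <- sum(abs(v[seq_len(n)] - tv[seq_len(n)]))
    extra <- abs(length(v) - length(tv)) / 2L
    -(d + extra * per_layer_penalty)
  }
}

#' Write a run history to CSV
#'
#' @param history The `history` data frame returned by [evolve()].
#' @param path Output path.
#' @return The data frame, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(history)
}
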