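test_that("population initialization has the configured size and bounds", {
  cfg <- ga_config(population_size = 20, max_layers = 6, seed = 5)
  set.seed(5)
  pop <- initialize_population(cfg)
  expect_length(pop$individuals, 20)
  expect_true(all(vapply(pop$individuals, function(i) is.na(i$fitness), logical(1))))
  lens <- vapply(pop$individuals, function(i) nrow(i$genome), integer(1))
  expect_true(all(lens >= 1 & lens <= 6))
  set.seed(5)
  pop2 <- initialize_population(cfg)
  expect_identical(lapply(pop$individuals, `[[`, "genome"),
                   lapply(pop2$individuals, `[[`, "genome"))
})

test_that("uniform crossover degenerates to a parent at p_c 0 and 1", {
  cfg <- ga_config()
  p1 <- conv_genome(list(c(10, 3), c(20, 5), c(30, 7)), cfg)
  p2 <- conv_genome(list(c(11, 2), c(21, 4), c(31, 6)), cfg)
  set.seed(1)
  expect_identical(uniform_crossover(p1, p2, 1), p1)
  expect_identical(uniform_crossover(p1, p2, 0), p2)
  expect_error(uniform_crossover(p1, conv_genome(list(c(5, 5)), cfg), 0.5),
               "equal-length")
})

test_that("uniform crossover gene origins match p_c within 3 sigma", {
  cfg <- ga_config()
  p1 <- conv_genome(list(c(10, 3), c(20, 5), c(30, 7)), cfg)
  p2 <- conv_genome(list(c(11, 2), c(21, 4), c(31, 6)), cfg)
  set.seed(2)
  n <- 10000
  origins <- matrix(0L, n, 6)
  v1 <- encode_genome(p1)
  for (t in seq_len(n))
    origins[t, ] <- as.integer(encode_genome(uniform_crossover(p1, p2, 0.5)) == v1)
  freq <- colMeans(origins)
  sigma <- sqrt(0.25 / n)
  expect_true(all(abs(freq - 0.5) <= 3 * sigma))
})

test_that("length crossover draws child lengths uniformly over the parent range", {
  cfg <- ga_config(max_layers = 6)
  p4 <- conv_genome(lapply(1:4, function(i) c(10 + i, 3)), cfg)
  p6 <- conv_genome(lapply(1:6, function(i) c(20 + i, 5)), cfg)
  set.seed(3)
  n <- 10000
  lens <- integer(n)
  for (t in seq_len(n)) lens[t] <- nrow(length_crossover(p4, p6, cfg))
  expect_true(all(lens %in% 4:6))
  freq <- tabulate(lens, 6)[4:6] / n
  sigma <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) <= 3 * sigma))
  # equal lengths: degenerate interval; identical parents: identical child
  expect_identical(nrow(length_crossover(p4, p4, cfg)), 4L)
  expect_identical(length_crossover(p6, p6, cfg), p6)
})

test_that("child layers come from a parent possessing that layer", {
  cfg <- ga_config(max_layers = 6)
  p1 <- conv_genome(lapply(1:3, function(i) c(i, 1)), cfg)
  p2 <- conv_genome(lapply(1:5, function(i) c(100 + i, 2)), cfg)
  set.seed(4)
  for (t in 1:200) {
    ch <- length_crossover(p1, p2, cfg)
    for (i in seq_len(nrow(ch))) {
      from1 <- i <= 3 && all(ch[i, ] == unclass(p1)[i, ])
      from2 <- i <= 5 && all(ch[i, ] == unclass(p2)[i, ])
      expect_true(from1 || from2)
    }
  }
})

test_that("zero-rate mutation is the identity and clamping holds at bounds", {
  cfg <- ga_config(mutation_rate = 0)
  g <- conv_genome(list(c(10, 3), c(256, 7)), cfg)
  set.seed(5)
  expect_identical(mutate_genome(g, cfg), g)
  # rate 1 with all genes at the upper bound: perturbations clamp back inside
  cfg1 <- ga_config(mutation_rate = 1)
  gmax <- conv_genome(list(c(256, 7)), cfg1)
  for (t in 1:50) {
    m <- mutate_genome(gmax, cfg1)
    expect_true(m[1, "filters"] <= 256 && m[1, "kernel"] <= 7)
    expect_true(m[1, "filters"] >= 1 && m[1, "kernel"] >= 1)
  }
})

test_that("mutation magnitudes match the delta distribution's mean", {
  # uniform on {-d..-1, 1..d} has mean |delta| = (d + 1) / 2
  cfg <- ga_config(mutation_rate = 1, max_filters = 101, max_filter_size = 101,
                   mutation_delta = list(family = "uniform_int", scale = "auto"))
  d <- ceiling(0.1 * (101 - 1))  # 10
  g <- conv_genome(list(c(51, 51)), cfg)
  set.seed(6)
  n <- 10000
  changes <- matrix(0, n, 2)
  for (t in seq_len(n))
    changes[t, ] <- abs(encode_genome(mutate_genome(g, cfg)) - c(51, 51))
  # far from bounds, no clamping: mean |change| = (d+1)/2 = 5.5
  m_expect <- (d + 1) / 2
  sd_delta <- sqrt(sum((1:d)^2) / d - m_expect^2)
  tol <- 3 * sd_delta / sqrt(n)
  expect_lt(abs(mean(changes[, 1]) - m_expect), tol)
  expect_lt(abs(mean(changes[, 2]) - m_expect), tol)
})

test_that("survivor selection equals a brute-force sort with deterministic ties", {
  cfg <- ga_config(max_layers = 3, max_filters = 20, max_filter_size = 5)
  set.seed(7)
  inds <- lapply(1:20, function(i)
    new_individual(random_genome(cfg), fitness = sample(1:5, 1),
                   generation_born = sample(0:3, 1)))
  pop <- structure(list(individuals = inds, generation = 3L), class = "population")
  surv <- select_survivors(pop, 5)
  # brute force: full order by (-fitness, born, encoding string)
  keyfn <- function(i) paste(sprintf("%010d", encode_genome(i$genome)), collapse = ",")
  ord <- order(-vapply(inds, `[[`, numeric(1), "fitness"),
               vapply(inds, `[[`, integer(1), "generation_born"),
               vapply(inds, keyfn, character(1)))
  expect_identical(surv$individuals, inds[ord[1:5]])
  expect_identical(select_survivors(pop, 20)$individuals, inds[ord])
  expect_identical(select_survivors(pop, 1)$individuals[[1]], inds[[ord[1]]])
})

test_that("selection refuses unevaluated individuals", {
  cfg <- ga_config()
  pop <- structure(list(individuals = list(new_individual(random_genome(cfg))),
                        generation = 0L), class = "population")
  expect_error(select_survivors(pop, 1), "evaluated")
})

test_that("a constant fitness landscape stops after patience + 1 generations", {
  for (pat in c(1L, 3L)) {
    cfg <- tiny_space_config(patience = pat, seed = 11)
    res <- evolve(cfg, function(g) 1)
    expect_identical(res$stop_reason, "plateau")
    expect_identical(nrow(res$history), pat + 1L)
  }
})

test_that("elitism makes best fitness non-decreasing and runs reproducible", {
  target_cfg <- tiny_space_config(seed = 1)
  target <- conv_genome(list(c(4, 2), c(6, 1)), target_cfg)
  fit <- surrogate_fitness_l1(target, target_cfg)
  for (seed in 1:20) {
    cfg <- tiny_space_config(seed = seed, elitism_k = 2)
    res <- evolve(cfg, fit)
    expect_true(all(diff(res$history$best_fitness) >= 0))
  }
  cfg <- tiny_space_config(seed = 123)
  r1 <- evolve(cfg, fit)
  r2 <- evolve(cfg, fit)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best$genome, r2$best$genome)
})

test_that("every genome produced during a run satisfies its bounds", {
  cfg <- tiny_space_config(seed = 3, structural_mutation = TRUE,
                           mutation_rate = 0.3)
  seen <- list()
  fit <- function(g) {
    validate_genome(g)
    seen[[length(seen) + 1L]] <<- g
    -sum(encode_genome(g))
  }
  evolve(cfg, fit)
  expect_gt(length(seen), 20)
  for (g in seen) {
    expect_true(nrow(g) >= 1 && nrow(g) <= cfg$max_layers)
    expect_true(all(g[, "filters"] <= cfg$max_filters))
    expect_true(all(g[, "kernel"] <= cfg$max_filter_size))
  }
})

test_that("the GA recovers a hidden optimum verified by enumeration", {
  cfg0 <- tiny_space_config()
  target <- conv_genome(list(c(4, 2), c(6, 1)), cfg0)
  fit <- surrogate_fitness_l1(target, cfg0)
  # exhaustive check that the target is the unique global optimum
  space <- enumerate_tiny_space(cfg0)
  vals <- vapply(space, function(v) fit(decode_genome(v, cfg0)), numeric(1))
  expect_identical(sum(vals == max(vals)), 1L)
  expect_identical(space[[which.max(vals)]], encode_genome(target))
  hits <- 0L
  for (seed in 1:20) {
    res <- evolve(tiny_space_config(seed = seed), fit)
    if (identical(unclass(res$best$genome), unclass(target))) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 95% of 20 seeded runs
})

test_that("a failing fitness function aborts with genome context", {
  cfg <- tiny_space_config(seed = 2)
  expect_error(evolve(cfg, function(g) stop("boom")),
               "generation 0 on genome.*boom")
})
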