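test_that("a tiny CNN learns the separable synthetic task", {
  sp <- tiny_split_data(n_per_class = 60, image_size = c(16, 16), lift = 0.5,
                        seed = 61)
  # separability certified independently of the network
  orc <- oracle_threshold_classifier(sp$train, sp$test)
  expect_gte(orc$test_accuracy, 0.9)
  g <- conv_genome(list(c(8, 3), c(8, 3)), ga_config())
  spec <- build_cnn_spec(g, c(16, 16, 1))
  res <- train_and_score(spec, sp, train_budget(epochs = 10, seed = 1))
  expect_gte(res$test_accuracy, 0.85)
  expect_gte(res$train_accuracy, 0.9)
  expect_equal(res$test_accuracy + res$error_rate, 1, tolerance = 1e-9)
  expect_true(is.finite(res$loss) && res$loss >= 0)
})

test_that("a zero-lift task trains to chance-level accuracy", {
  sp <- tiny_split_data(n_per_class = 60, image_size = c(16, 16), lift = 0,
                        seed = 62)
  g <- conv_genome(list(c(4, 3)), ga_config())
  spec <- build_cnn_spec(g, c(16, 16, 1))
  accs <- vapply(1:3, function(seed)
    train_and_score(spec, sp, train_budget(epochs = 3, seed = seed))$test_accuracy,
    numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("longer training does not hurt mean training accuracy", {
  sp <- tiny_split_data(n_per_class = 40, image_size = c(16, 16), lift = 0.5,
                        seed = 63)
  g <- conv_genome(list(c(6, 3)), ga_config())
  spec <- build_cnn_spec(g, c(16, 16, 1))
  acc_at <- function(epochs) mean(vapply(1:3, function(seed)
    train_and_score(spec, sp, train_budget(epochs = epochs, seed = seed))$train_accuracy,
    numeric(1)))
  expect_gte(acc_at(8) + 0.02, acc_at(1))
})

test_that("training is reproducible under a fixed budget seed", {
  sp <- tiny_split_data(n_per_class = 20, image_size = c(8, 8), seed = 64)
  g <- conv_genome(list(c(4, 3)), ga_config())
  spec <- build_cnn_spec(g, c(8, 8, 1))
  r1 <- train_and_score(spec, sp, train_budget(epochs = 2, seed = 5))
  r2 <- train_and_score(spec, sp, train_budget(epochs = 2, seed = 5))
  expect_identical(unclass(r1), unclass(r2))
})

test_that("shape mismatches surface as fitness 0, not errors", {
  sp <- tiny_split_data(n_per_class = 10, image_size = c(4, 4), seed = 65)
  # a 6-layer genome needs 3 pools: 4x4 input is too small -> discarded
  g <- conv_genome(lapply(1:6, function(i) c(2, 3)), ga_config())
  f <- genome_fitness(g, sp, train_budget(epochs = 1, seed = 1),
                      input_shape = c(4, 4, 1))
  expect_identical(f, 0)
})

test_that("surrogate fitness bypasses training and is pure in the genome", {
  cfg <- tiny_space_config()
  target <- conv_genome(list(c(3, 2)), cfg)
  sfn <- surrogate_fitness_l1(target, cfg)
  g <- conv_genome(list(c(5, 1)), cfg)
  f1 <- genome_fitness(g, data = NULL, fitness_kind = "surrogate",
                       surrogate_fn = sfn)
  expect_identical(f1, sfn(g))
  expect_identical(f1, -(2 + 1))
  expect_identical(sfn(target), 0)
})

test_that("validation fitness matches the percentage-accuracy formula", {
  sp <- tiny_split_data(n_per_class = 30, image_size = c(8, 8), lift = 0.5,
                        seed = 66)
  g <- conv_genome(list(c(4, 3)), ga_config())
  spec <- build_cnn_spec(g, c(8, 8, 1))
  res <- train_and_score(spec, sp, train_budget(epochs = 4, seed = 2))
  f <- genome_fitness(g, sp, train_budget(epochs = 4, seed = 2),
                      input_shape = c(8, 8, 1))
  n_val <- length(sp$val$labels)
  expect_equal(f, fitness_accuracy_pct(round(res$val_accuracy * n_val), n_val),
               tolerance = 1e-9)
})

test_that("a dense head on the frozen backbone trains on the synthetic task", {
  sp <- tiny_split_data(n_per_class = 50, image_size = c(16, 16), lift = 0.6,
                        seed = 67)
  bb <- standin_backbone(c(16, 16, 1), seed = 42)
  cfg <- ga_config(min_neurons = 8, max_neurons = 64)
  h <- dense_genome(c(16, 16), cfg)
  spec <- build_head_spec(h, bb$feature_shape, dropout_rate = 0.2)
  res <- train_and_score(spec, sp, train_budget(epochs = 40, seed = 1),
                         backbone = bb)
  expect_gte(res$test_accuracy, 0.75)
})
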