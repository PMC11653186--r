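test_that("the six-layer optimum builds the canonical scaffold", {
  cfg <- ga_config()
  g <- decode_genome(c(224, 5, 112, 5, 208, 2, 135, 2, 35, 2, 104, 2), cfg)
  spec <- build_cnn_spec(g, c(64, 64, 1))
  counts <- spec_layer_counts(spec)
  expect_identical(counts[["conv"]], 6L)
  expect_identical(counts[["batch_norm"]], 6L)
  expect_identical(counts[["max_pool"]], 3L)
  expect_identical(counts[["flatten"]], 1L)
  expect_identical(counts[["output"]], 1L)
  convs <- Filter(function(l) l$kind == "conv", spec$layers)
  expect_identical(vapply(convs, `[[`, integer(1), "filters"),
                   c(224L, 112L, 208L, 135L, 35L, 104L))
  expect_identical(vapply(convs, `[[`, integer(1), "kernel"),
                   c(5L, 5L, 2L, 2L, 2L, 2L))
  # three pools: 64 -> 32 -> 16 -> 8
  out <- spec$layers[[length(spec$layers)]]
  expect_identical(out$output_shape, 1L)
  flat <- Filter(function(l) l$kind == "flatten", spec$layers)[[1]]
  expect_identical(flat$output_shape, 8L * 8L * 104L)
})

test_that("pool count follows floor(L / 2) and single-layer genomes have none", {
  cfg <- ga_config()
  g1 <- conv_genome(list(c(8, 3)), cfg)
  spec1 <- build_cnn_spec(g1, c(32, 32, 1))
  counts <- spec_layer_counts(spec1)
  expect_identical(counts[["conv"]], 1L)
  expect_identical(counts[["batch_norm"]], 1L)
  expect_identical(counts[["max_pool"]], 0L)
  for (L in 1:6) {
    g <- conv_genome(lapply(seq_len(L), function(i) c(4, 3)), cfg)
    counts <- spec_layer_counts(build_cnn_spec(g, c(64, 64, 1)))
    expect_identical(counts[["max_pool"]], L %/% 2L)
    expect_identical(counts[["conv"]], L)
  }
})

test_that("inputs too small for the pooling schedule are rejected by name", {
  cfg <- ga_config()
  g6 <- conv_genome(lapply(1:6, function(i) c(4, 3)), cfg)
  expect_error(build_cnn_spec(g6, c(4, 4, 1)), "too small.*3 max-pool")
  expect_silent(build_cnn_spec(g6, c(8, 8, 1)))
})

test_that("parameter counts match independent hand computations", {
  cfg <- ga_config()
  # one conv layer (2 filters, 3x3) on 8x8x1: conv 2*(9*1)+2 = 20,
  # batch norm 2*2 = 4, output (8*8*2)*1+1 = 129
  g <- conv_genome(list(c(2, 3)), cfg)
  spec <- build_cnn_spec(g, c(8, 8, 1))
  expect_identical(count_params(spec), 20L + 4L + 129L)
  # the full six-layer optimum on 64x64x1 against the per-layer formula
  g6 <- decode_genome(c(224, 5, 112, 5, 208, 2, 135, 2, 35, 2, 104, 2), cfg)
  expect_identical(count_params(build_cnn_spec(g6, c(64, 64, 1))),
                   as.integer(hand_count_params(c(224, 112, 208, 135, 35, 104),
                                                c(5, 5, 2, 2, 2, 2),
                                                c(64, 64, 1))))
  # random genomes against the same oracle
  set.seed(8)
  for (i in 1:20) {
    gr <- random_genome(ga_config(max_filters = 32, max_filter_size = 5))
    expect_identical(count_params(build_cnn_spec(gr, c(32, 32, 1))),
                     as.integer(hand_count_params(gr[, "filters"], gr[, "kernel"],
                                                  c(32, 32, 1))))
  }
})

test_that("dense parameter count follows in * out + out", {
  cfg <- ga_config(min_neurons = 1, max_neurons = 600)
  h <- dense_genome(3, cfg)
  spec <- build_head_spec(h, feature_shape = 4)
  # dense(4 -> 3) = 15, output(3 -> 1) = 4
  expect_identical(count_params(spec), 19L)
})

test_that("the dense head spec mirrors the frozen-backbone design", {
  cfg <- ga_config(min_neurons = 200, max_neurons = 600)
  h <- dense_genome(c(452, 574), cfg)
  spec <- build_head_spec(h, feature_shape = c(8, 8, 16))
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_identical(kinds, c("flatten", "dropout", "dense", "dense", "output"))
  expect_identical(spec$layers[[3]]$units, 452L)
  expect_identical(spec$layers[[4]]$units, 574L)
  expect_true(spec$frozen_backbone)
  expect_silent(build_head_spec(dense_genome(200, cfg), feature_shape = 64))
  expect_error(dense_genome(601, cfg), "600")
})

test_that("spec construction is pure and shapes stay positive", {
  cfg <- ga_config()
  set.seed(9)
  for (i in 1:10) {
    g <- random_genome(cfg)
    s1 <- build_cnn_spec(g, c(64, 64, 1))
    s2 <- build_cnn_spec(g, c(64, 64, 1))
    expect_identical(s1, s2)
    for (ly in s1$layers)
      expect_true(all(ly$output_shape >= 1))
  }
})
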