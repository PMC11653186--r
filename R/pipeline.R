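# End-to-end pipeline drivers behind the command-line entry point:
# simulate a dataset, optimize an architecture, evaluate a genome, report
# a run history.  Each driver writes a JSON run manifest sufficient to
# re-run it (bit-reproducibly in surrogate mode).

#' Read a YAML run configuration
#'
#' Recognized top-level blocks: `ga` ([ga_config()] fields), `synth`
#' ([synth_spec()] fields), `augment` ([augment_spec()] fields plus
#' `multiplier`), `budget` ([train_budget()] fields), `image` (`target_size`,
#' a 2-vector).  Missing blocks and fields fall back to the package
#' defaults, so an empty file is a valid configuration.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param seed Optional seed overriding the config's seeds.
#' @return A list with `ga`, `synth`, `augment`, `multiplier`, `budget`,
#'   `target_size`.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  fill <- function(fn, block, drop = character(0)) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    args <- args[setdiff(names(args), drop)]
    ok <- intersect(names(args), names(formals(fn)))
    bad <- setdiff(names(args), ok)
    if (length(bad))
      stop(sprintf("unknown %s field(s): %s", block, paste(bad, collapse = ", ")),
           call. = FALSE)
    do.call(fn, args[ok])
  }
  ga <- fill(ga_config, "ga")
  synth <- fill(synth_spec, "synth")
  aug <- fill(augment_spec, "augment", drop = "multiplier")
  multiplier <- raw$augment$multiplier
  if (is.null(multiplier)) multiplier <- 0L
  budget <- fill(train_budget, "budget")
  target_size <- raw$image$target_size
  if (is.null(target_size)) target_size <- c(32L, 32L)
  if (!is.null(seed)) {
    ga$seed <- as.integer(seed)
    synth$seed <- as.integer(seed)
    budget$seed <- as.integer(seed)
  }
  list(ga = ga, synth = synth, augment = aug, multiplier = as.integer(multiplier),
       budget = budget, target_size = as.integer(target_size))
}

write_manifest <- function(path, ...) {
  manifest <- list(package_version = as.character(utils::packageVersion("evocnn")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), ...)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Simulate a synthetic dataset tree
#'
#' Generates a balanced two-class image pool from the config's `synth`
#' block, splits it with the canonical stratified fractions
#' (4192/624/1040 of 5856 — i.e. ~71.6% train, ~10.7% test, ~17.8% val)
#' and writes the `{split}/{NORMAL,PNEUMONIA}` PNG tree plus a manifest.
#'
#' @param config_path YAML config (or `NULL` for defaults).
#' @param out_dir Output directory for the tree.
#' @param seed Optional seed override.
#' @return The manifest list, invisibly.
#' @export
run_simulate <- function(config_path = NULL, out_dir, seed = NULL) {
  cfg <- read_run_config(config_path, seed)
  if (cfg$synth$n_per_class < 1L)
    stop("n_per_class must be >= 1 to simulate a dataset", call. = FALSE)
  pool <- generate_images(cfg$synth)
  splits <- stratified_split(pool, DEFAULT_SPLIT_FRACTIONS, seed = cfg$synth$seed)
  write_dataset_tree(splits, out_dir)
  counts <- lapply(splits, function(s) length(s$images))
  write_manifest(file.path(out_dir, "manifest.json"),
                 command = "simulate", seed = cfg$synth$seed,
                 synth = unclass(cfg$synth), split_sizes = counts)
}

# Canonical split proportions of the 5856-image radiograph corpus.
DEFAULT_SPLIT_FRACTIONS <- c(train = 4192, test = 624, val = 1040) / 5856

#' Run the architecture search on a dataset
#'
#' Loads the dataset tree, optionally augments the training split (never
#' the validation or test splits), then evolves convolutional chromosomes
#' with [evolve()] using validation-split accuracy as fitness.  The best
#' genome is finally retrained at the full budget and scored on the held-
#' out test split.  Writes `history.csv`, `best_genome.json` and
#' `manifest.json` into `out_dir`.
#'
#' @param config_path YAML config (or `NULL` for defaults).
#' @param data_dir Dataset root in the `{split}/{class}` layout.
#' @param out_dir Output directory.
#' @param seed Optional seed override.
#' @param final_epochs Epochs for the final retrain of the best genome
#'   (default 3x the search budget).
#' @return A list with `best`, `history`, `stop_reason`, `final_eval`,
#'   invisibly.
#' @export
run_optimize <- function(config_path = NULL, data_dir, out_dir, seed = NULL,
                         final_epochs = NULL) {
  cfg <- read_run_config(config_path, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- load_dataset(data_dir, target_size = cfg$target_size)
  for (nm in c("train", "test", "val"))
    if (is.null(data[[nm]])) stop(sprintf("dataset has no %s split", nm),
                                  call. = FALSE)
  sizes_loaded <- vapply(data[c("train", "val", "test")],
                         function(s) length(s$images), integer(1))
  # only the training split is ever augmented; val/test stay untouched
  if (cfg$multiplier > 0)
    data$train <- augment(data$train, cfg$augment, cfg$multiplier,
                          seed = cfg$ga$seed)
  stopifnot(length(data$val$images) == sizes_loaded[["val"]],
            length(data$test$images) == sizes_loaded[["test"]])
  input_shape <- c(cfg$target_size, 1L)
  fit_fn <- function(g) genome_fitness(g, data, cfg$budget,
                                       fitness_kind = cfg$ga$fitness_kind,
                                       input_shape = input_shape)
  res <- evolve(cfg$ga, fit_fn)
  if (is.null(final_epochs)) final_epochs <- 3L * cfg$budget$epochs
  final_budget <- train_budget(epochs = final_epochs,
                               batch_size = cfg$budget$batch_size,
                               learning_rate = cfg$budget$learning_rate,
                               seed = cfg$budget$seed)
  final_spec <- build_cnn_spec(res$best$genome, input_shape)
  final_eval <- train_and_score(final_spec, data, final_budget)
  write_history_csv(res$history, file.path(out_dir, "history.csv"))
  writeLines(as.character(genome_to_json(res$best$genome)),
             file.path(out_dir, "best_genome.json"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 command = "optimize", seed = cfg$ga$seed,
                 ga = cfg$ga[setdiff(names(cfg$ga), "cost_weights")],
                 budget = unclass(cfg$budget),
                 augment_multiplier = cfg$multiplier,
                 split_sizes = as.list(sizes_loaded),
                 train_size_after_augment = length(data$train$images),
                 stop_reason = res$stop_reason,
                 best_genome = jsonlite::fromJSON(genome_to_json(res$best$genome)),
                 best_search_fitness = res$best$fitness,
                 final_eval = unclass(final_eval))
  invisible(list(best = res$best, history = res$history,
                 stop_reason = res$stop_reason, final_eval = final_eval))
}

#' Train and evaluate a single genome at full budget
#'
#' @param genome_json Path to a genome JSON (as written by
#'   [run_optimize()]), or a JSON string.
#' @param data_dir Dataset root.
#' @param out_dir Output directory for `eval.csv` and `manifest.json`.
#' @param config_path YAML config (or `NULL`).
#' @param seed Optional seed override.
#' @return The [eval_result()], invisibly.
#' @export
run_evaluate <- function(genome_json, data_dir, out_dir, config_path = NULL,
                         seed = NULL) {
  cfg <- read_run_config(config_path, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  txt <- if (file.exists(genome_json)) paste(readLines(genome_json), collapse = "")
         else genome_json
  g <- genome_from_json(txt, cfg$ga)
  data <- load_dataset(data_dir, target_size = cfg$target_size)
  spec <- build_cnn_spec(g, c(cfg$target_size, 1L))
  res <- train_and_score(spec, data, cfg$budget)
  write_eval_csv(res, file.path(out_dir, "eval.csv"), epochs = cfg$budget$epochs)
  write_manifest(file.path(out_dir, "manifest.json"),
                 command = "evaluate", seed = cfg$budget$seed,
                 genome = jsonlite::fromJSON(as.character(genome_to_json(g))),
                 budget = unclass(cfg$budget), eval = unclass(res))
  invisible(res)
}

#' Render a run history as a fitness-vs-generation table
#'
#' @param history_csv Path to a `history.csv` written by [run_optimize()].
#' @return The history data frame, invisibly; the table is printed.
#' @export
run_report <- function(history_csv) {
  h <- utils::read.csv(history_csv, stringsAsFactors = FALSE)
  cat(sprintf("%-11s %-14s %-14s %s\n", "generation", "best_fitness",
              "mean_fitness", "best_genome"))
  for (i in seq_len(nrow(h)))
    cat(sprintf("%-11d %-14.4f %-14.4f %s\n", h$generation[i],
                h$best_fitness[i], h$mean_fitness[i], h$best_genome_json[i]))
  invisible(h)
}
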