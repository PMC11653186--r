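# Turn an architecture spec plus labeled image sets into an evaluation
# result — the GA's real fitness evaluator — with a deterministic
# surrogate mode for fast tests.

#' Training budget
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam step size.
#' @param seed Integer seed for weight initialization, shuffling and
#'   dropout.
#' @return An object of class `train_budget`.
#' @export
train_budget <- function(epochs = 5L, batch_size = 32L, learning_rate = 1e-3,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_budget")
}

#' Train a model and score it
#'
#' Minimizes binary cross-entropy with Adam for the given budget and
#' reports train/validation/test accuracies, the final mean training loss,
#' and the error rate (misclassification fraction) on the test split.
#' Probabilities above 0.5 predict class 1.  Fully seeded.  A structured
#' failure (shape mismatch, non-finite loss) raises a condition of class
#' `evocnn_train_failure`, which [genome_fitness()] maps to fitness 0.
#'
#' @param spec An `arch_spec` from [build_cnn_spec()] or
#'   [build_head_spec()].
#' @param data Named list with `train`, `val`, `test`
#'   [labeled_image_set()]s (for a frozen-backbone spec, pass the raw
#'   images and the `backbone`).
#' @param budget A [train_budget()].
#' @param backbone Optional [standin_backbone()]; required when
#'   `spec$frozen_backbone` is `TRUE`: images are passed through the
#'   frozen extractor once and only the head is trained.
#' @return An [eval_result()].
#' @export
train_and_score <- function(spec, data, budget = train_budget(), backbone = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  for (nm in c("train", "val", "test"))
    if (is.null(data[[nm]]))
      stop(sprintf("data must contain a '%s' set", nm), call. = FALSE)
  set.seed(budget$seed)
  to_x <- function(set) {
    x <- stack_images(set$images)
    if (spec$frozen_backbone) {
      if (is.null(backbone))
        stop("frozen-backbone spec needs a backbone", call. = FALSE)
      x <- backbone_features(backbone, x)
    }
    x
  }
  x_tr <- to_x(data$train); y_tr <- data$train$labels
  fit <- nn_fit(spec, x_tr, y_tr, budget$epochs, budget$batch_size,
                budget$learning_rate)
  acc <- function(set, x) {
    p <- nn_predict(fit$net, x)
    mean(as.integer(p > 0.5) == set$labels)
  }
  train_acc <- acc(data$train, x_tr)
  p_val <- nn_predict(fit$net, to_x(data$val))
  pred_val <- as.integer(p_val > 0.5)
  val_acc <- mean(pred_val == data$val$labels)
  x_te <- to_x(data$test)
  p_te <- nn_predict(fit$net, x_te)
  pred_te <- as.integer(p_te > 0.5)
  res <- eval_result(train_accuracy = train_acc,
                     test_accuracy = mean(pred_te == data$test$labels),
                     loss = fit$final_loss,
                     error_rate = error_rate(data$test$labels, pred_te),
                     val_accuracy = val_acc)
  attr(res, "val_predictions") <- pred_val
  res
}

#' Fitness of a genome under a given fitness kind
#'
#' Builds the architecture, trains it on the training split and scores the
#' validation split (the test split stays held out during evolution).
#' Under `"accuracy_pct"` the fitness is the percentage of correct
#' validation predictions; under `"confusion"` it is TP / (TP + FP + FN)
#' on the validation split.  `"surrogate"` requires `surrogate_fn` and
#' bypasses training entirely.  Any training failure yields fitness 0, so
#' broken configurations are simply discarded by selection.
#'
#' @param g A genome.
#' @param data Named list of `train`, `val`, `test` sets.
#' @param budget A [train_budget()].
#' @param fitness_kind `"accuracy_pct"`, `"confusion"` or `"surrogate"`.
#' @param input_shape Image shape for [build_cnn_spec()].
#' @param surrogate_fn Function genome -> numeric, used when
#'   `fitness_kind = "surrogate"`.
#' @param backbone Optional frozen backbone for `dense_genome`s.
#' @return A finite numeric fitness (higher is better).
#' @export
genome_fitness <- function(g, data, budget = train_budget(),
                           fitness_kind = "accuracy_pct",
                           input_shape = NULL, surrogate_fn = NULL,
                           backbone = NULL) {
  if (fitness_kind == "surrogate") {
    if (is.null(surrogate_fn)) stop("surrogate fitness needs surrogate_fn",
                                    call. = FALSE)
    return(surrogate_fn(g))
  }
  res <- tryCatch({
    if (inherits(g, "dense_genome")) {
      if (is.null(backbone)) stop("dense genome needs a backbone", call. = FALSE)
      spec <- build_head_spec(g, backbone$feature_shape)
    } else {
      if (is.null(input_shape))
        input_shape <- c(dim(data$train$images[[1]]), 1L)
      spec <- build_cnn_spec(g, input_shape)
    }
    train_and_score(spec, data, budget, backbone = backbone)
  },
    evocnn_train_failure = function(e) NULL,
    error = function(e) {
      # shape errors from build/training count as a discarded configuration
      if (grepl("too small|shape|collapses", conditionMessage(e))) NULL
      else stop(e)
    })
  if (is.null(res)) return(0)
  n_val <- length(data$val$labels)
  if (fitness_kind == "confusion")
    return(confusion_fitness_from_sets(res, data))
  fitness_accuracy_pct(round(res$val_accuracy * n_val), n_val)
}

# Confusion fitness scores the validation predictions attached to the
# eval_result by train_and_score.
confusion_fitness_from_sets <- function(res, data) {
  pred <- attr(res, "val_predictions")
  if (is.null(pred))
    stop("confusion fitness requires validation predictions", call. = FALSE)
  y <- data$val$labels
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  if (tp + fp + fn == 0) return(1)  # no positives anywhere: nothing missed
  fitness_confusion(tp, fp, fn)
}
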