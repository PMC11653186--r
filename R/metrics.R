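# Scoring formulas: confusion-matrix fitness, percentage accuracy,
# binary and categorical cross-entropy, error rate and architecture cost.

PROB_EPS <- 1e-7

#' Confusion-matrix fitness
#'
#' F = TP / (TP + FP + FN): the fraction of true detections among all
#' positive calls and missed cases (true negatives do not enter).  For a
#' pneumonia screen, TP are correctly flagged pneumonia images, FP normal
#' images flagged as pneumonia and FN missed pneumonia images.
#'
#' @param tp,fp,fn Nonnegative integer counts; `tp + fp + fn` must be > 0.
#' @return Fitness in \[0, 1\].
#' @export
#' @examples
#' fitness_confusion(50, 25, 25)  # 0.5
fitness_confusion <- function(tp, fp, fn) {
  counts <- c(tp, fp, fn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  denom <- tp + fp + fn
  if (denom == 0) stop("fitness undefined: TP + FP + FN is zero", call. = FALSE)
  tp / denom
}

#' Percentage-accuracy fitness
#'
#' Fitness = 100 * correct / total, the variant used to compare candidate
#' architectures during evolution.
#'
#' @param correct Number of correct predictions, `0 <= correct <= total`.
#' @param total Number of predictions, >= 1.
#' @return Accuracy as a percentage in \[0, 100\].
#' @export
fitness_accuracy_pct <- function(correct, total) {
  if (total < 1) stop("total must be >= 1", call. = FALSE)
  if (correct < 0 || correct > total)
    stop("correct must lie in [0, total]", call. = FALSE)
  100 * correct / total
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` with natural logarithms;
#' probabilities are clipped to `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param labels Binary (0/1) vector.
#' @param probs Predicted probabilities of class 1, same length.
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' bce_loss(c(1, 0), c(0.9, 0.1))  # -(log(0.9) + log(0.9)) / 2
bce_loss <- function(labels, probs) {
  if (length(labels) != length(probs))
    stop("labels and probs must have equal length", call. = FALSE)
  if (length(labels) == 0) stop("empty input", call. = FALSE)
  p <- pmin(pmax(probs, PROB_EPS), 1 - PROB_EPS)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Categorical cross-entropy loss
#'
#' Mean over samples of `-sum_j t_ij log(g_ij)` for one-hot targets `t` and
#' row-stochastic predicted probabilities `g` (rows must sum to 1 within
#' 1e-6); probabilities are clipped as in [bce_loss()].
#'
#' @param onehot N x K binary matrix of one-hot targets.
#' @param probs N x K matrix of predicted class probabilities.
#' @return Nonnegative scalar loss.
#' @export
cce_loss <- function(onehot, probs) {
  onehot <- as.matrix(onehot); probs <- as.matrix(probs)
  if (!all(dim(onehot) == dim(probs)))
    stop("onehot and probs must have identical dimensions", call. = FALSE)
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6))
    stop(sprintf("probability row %d does not sum to 1 (sum %.8f)",
                 which(abs(rs - 1) > 1e-6)[1], rs[which(abs(rs - 1) > 1e-6)[1]]),
         call. = FALSE)
  g <- pmin(pmax(probs, PROB_EPS), 1 - PROB_EPS)
  mean(-rowSums(onehot * log(g)))
}

#' Label error rate
#'
#' Mean absolute difference between the true and predicted label vectors;
#' for hard binary labels this is the misclassification fraction.
#'
#' @param real_labels,predicted_labels Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
error_rate <- function(real_labels, predicted_labels) {
  if (length(real_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  mean(abs(real_labels - predicted_labels))
}

#' Architecture cost
#'
#' Cost(L, F) = alpha * L + beta * F + gamma * E, a weighted sum of the
#' layer count L, the total filter count F and the error rate E, used to
#' compare evolved architectures by size as well as accuracy.
#'
#' @param L Number of convolutional layers (>= 0).
#' @param F_total Total number of filters across layers (>= 0).
#' @param E Error rate (>= 0).
#' @param w A [cost_weights()].
#' @return Scalar cost.
#' @export
#' @examples
#' arch_cost(6, 818, 0.1, cost_weights(1, 1, 1))  # 824.1
arch_cost <- function(L, F_total, E, w) {
  if (!inherits(w, "cost_weights")) w <- do.call(cost_weights, as.list(w))
  if (L < 0 || F_total < 0 || E < 0)
    stop("L, F_total and E must be nonnegative", call. = FALSE)
  w$alpha * L + w$beta * F_total + w$gamma * E
}

#' Evaluation result of one trained model
#'
#' @param train_accuracy,test_accuracy Fractions in \[0, 1\].
#' @param loss Final training loss (nonnegative).
#' @param error_rate Misclassification fraction on the test split.
#' @param val_accuracy Optional validation-split accuracy (used as the
#'   fitness signal during evolution so the test split stays held out).
#' @return An object of class `eval_result`.
#' @export
eval_result <- function(train_accuracy, test_accuracy, loss, error_rate,
                        val_accuracy = NA_real_) {
  accs <- c(train_accuracy, test_accuracy)
  if (any(accs < 0 | accs > 1, na.rm = TRUE))
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  structure(list(train_accuracy = train_accuracy,
                 test_accuracy = test_accuracy,
                 loss = loss,
                 error_rate = error_rate,
                 val_accuracy = val_accuracy),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> train %.4f | val %s | test %.4f | loss %.4f | error %.4f\n",
              x$train_accuracy,
              if (is.na(x$val_accuracy)) "NA" else sprintf("%.4f", x$val_accuracy),
              x$test_accuracy, x$loss, x$error_rate))
  invisible(x)
}

#' Write evaluation results as CSV rows
#'
#' @param results A list of `eval_result` objects (or one).
#' @param path Output CSV path.
#' @param epochs Optional epoch count column.
#' @return The data frame written, invisibly.
#' @export
write_eval_csv <- function(results, path, epochs = NA_integer_) {
  if (inherits(results, "eval_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(epochs = epochs,
               training_accuracy = r$train_accuracy,
               test_accuracy = r$test_accuracy,
               loss = r$loss,
               error_rate = r$error_rate)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
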