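#' Confusion-matrix counts
#'
#' @param actual,predicted Binary (0/1) vectors of equal length.
#' @return List with integer fields `tp`, `tn`, `fp`, `fn` summing to the
#'   number of instances.
#' @export
confusion_counts <- function(actual, predicted) {
  check_binary(actual, NULL, "actual")
  check_binary(predicted, length(actual), "predicted")
  if (length(actual) < 1L) stop("confusion_counts(): empty input", call. = FALSE)
  tp <- sum(predicted * actual)
  fp <- sum(predicted) - tp
  fn <- sum(actual) - tp
  tn <- length(actual) - tp - fp - fn
  list(tp = as.integer(tp), tn = as.integer(tn),
       fp = as.integer(fp), fn = as.integer(fn))
}

#' Matthews correlation coefficient
#'
#' \eqn{(tp \cdot tn - fp \cdot fn) / \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}};
#' defined as 0 whenever any factor of the radicand is 0, keeping the value
#' bounded and deterministic for degenerate predictions.
#'
#' @inheritParams confusion_counts
#' @return Scalar in \[-1, 1\].
#' @export
mcc <- function(actual, predicted) {
  cc <- confusion_counts(actual, predicted)
  # doubles: integer products overflow at M ~ 2^15
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' F1 score
#'
#' Harmonic mean of precision `tp/(tp+fp)` and recall `tp/(tp+fn)`;
#' defined as 0 when `tp = 0`.
#'
#' @inheritParams confusion_counts
#' @return Scalar in \[0, 1\].
#' @export
f1_score <- function(actual, predicted) {
  cc <- confusion_counts(actual, predicted)
  if (cc$tp == 0L) return(0)
  precision <- cc$tp / (cc$tp + cc$fp)
  recall <- cc$tp / (cc$tp + cc$fn)
  2 * precision * recall / (precision + recall)
}

#' Classification accuracy
#'
#' @inheritParams confusion_counts
#' @return `(tp + tn) / M`, a scalar in \[0, 1\].
#' @export
accuracy <- function(actual, predicted) {
  cc <- confusion_counts(actual, predicted)
  (cc$tp + cc$tn) / length(actual)
}

#' False-negative and false-positive rates
#'
#' `fnr = fn / (tp + fn)` and `fpr = fp / (tn + fp)`. When a rate's
#' denominator is 0 (no actual positives, or no actual negatives) it is
#' reported as 0 and flagged in the `"undefined"` attribute.
#'
#' @inheritParams confusion_counts
#' @return Named numeric vector `c(fnr =, fpr =)` with an `"undefined"`
#'   attribute (logical length 2) marking rates whose denominator was 0.
#' @export
error_rates <- function(actual, predicted) {
  cc <- confusion_counts(actual, predicted)
  npos <- cc$tp + cc$fn
  nneg <- cc$tn + cc$fp
  fnr <- if (npos > 0L) cc$fn / npos else 0
  fpr <- if (nneg > 0L) cc$fp / nneg else 0
  out <- c(fnr = fnr, fpr = fpr)
  attr(out, "undefined") <- c(fnr = npos == 0L, fpr = nneg == 0L)
  out
}

#' Rank-based ROC-AUC
#'
#' Probability that a uniformly chosen positive instance receives a higher
#' score than a uniformly chosen negative one, with ties counted 1/2
#' (the Mann-Whitney statistic divided by `n1 * n0`).
#'
#' @param actual Binary (0/1) vector; both classes must be present.
#' @param scores Numeric score vector (probabilities or hard labels).
#' @return Scalar in \[0, 1\].
#' @export
roc_auc <- function(actual, scores) {
  check_binary(actual, NULL, "actual")
  if (length(scores) != length(actual)) {
    stop("roc_auc(): length mismatch", call. = FALSE)
  }
  n1 <- sum(actual == 1)
  n0 <- sum(actual == 0)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc(): both classes must be present", call. = FALSE)
  }
  r <- rank(scores)                     # midranks handle ties as 1/2
  (sum(r[actual == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean residual error between labels and probabilities
#'
#' `mode = "squared"` gives the mean of squared residuals (the literal
#' printed pseudocode); `mode = "absolute"` the mean of absolute residuals
#' (the metric's name). Both are 0 iff the probabilities equal the labels.
#'
#' @param actual Binary (0/1) vector.
#' @param probabilities Numeric vector in \[0, 1\], same length.
#' @param mode `"squared"` (default) or `"absolute"`.
#' @return Non-negative scalar.
#' @export
mean_error <- function(actual, probabilities,
                       mode = c("squared", "absolute")) {
  mode <- match.arg(mode)
  check_binary(actual, NULL, "actual")
  if (length(actual) == 0L) stop("mean_error(): empty input", call. = FALSE)
  if (length(probabilities) != length(actual) ||
      any(probabilities < 0) || any(probabilities > 1)) {
    stop("mean_error(): probabilities must lie in [0, 1] and match length",
         call. = FALSE)
  }
  r <- actual - probabilities
  if (mode == "squared") mean(r^2) else mean(abs(r))
}

#' Fitness specification
#'
#' Selects the maximized objective used to score candidate parameter
#' vectors: `"f1"` and `"mcc"` score hard (rounded) predictions, `"error"`
#' maps a mean residual error e to `1/(1 + e)`, `"xent"` maps the summed
#' cross-entropy cost J to `1/(1 + J)`. All four are finite and
#' higher-is-better.
#'
#' @param id One of `"f1"`, `"mcc"`, `"error"`, `"xent"`.
#' @param error_mode Residual mode for `id = "error"`: `"squared"`
#'   (default) or `"absolute"`.
#' @return Object of class `fitness_spec`.
#' @export
fitness_spec <- function(id = c("f1", "mcc", "error", "xent"),
                         error_mode = c("squared", "absolute")) {
  id <- match.arg(id)
  error_mode <- match.arg(error_mode)
  structure(list(id = id, error_mode = error_mode), class = "fitness_spec")
}

#' Fitness-evaluation counter
#'
#' A mutable counter tracking how many candidate evaluations have been
#' spent; the optimizers stop once it reaches the `MEN` budget. Every call
#' to [eval_fitness()] advances it by the number of candidate rows scored.
#'
#' @return Environment of class `eval_counter` with field `n`.
#' @export
new_eval_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  class(e) <- c("eval_counter", "environment")
  e
}

#' Batched fitness evaluation
#'
#' Scores each row of a candidate parameter batch against `(X, y)` under
#' the given [fitness_spec()] and advances the evaluation counter by the
#' number of rows.
#'
#' @param spec A [fitness_spec()].
#' @param theta Parameter vector or `K x D` batch matrix.
#' @param X Feature matrix `M x N`.
#' @param y Binary labels, length `M`.
#' @param counter Optional [new_eval_counter()]; incremented by `K`.
#' @return Numeric fitness vector of length `K`, finite, higher is better.
#' @export
eval_fitness <- function(spec, theta, X, y, counter = NULL) {
  stopifnot(inherits(spec, "fitness_spec"))
  W <- as_param_batch(theta)
  X <- as.matrix(X)
  check_binary(y, nrow(X), "y")
  P <- predict_proba(W, X)              # K x M
  if (!is.matrix(P)) P <- matrix(P, nrow = 1L)
  K <- nrow(P)
  f <- switch(spec$id,
    f1 = , mcc = {
      pred <- P >= 0.5                  # K x M logical
      tp <- as.numeric(pred %*% y)
      fp <- rowSums(pred) - tp
      fn <- sum(y) - tp
      tn <- length(y) - tp - fp - fn
      if (spec$id == "f1") {
        out <- numeric(K)
        ok <- tp > 0
        out[ok] <- 2 * tp[ok] / (2 * tp[ok] + fp[ok] + fn[ok])
        out
      } else {
        denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
        out <- numeric(K)
        ok <- denom > 0
        out[ok] <- (tp[ok] * tn[ok] - fp[ok] * fn[ok]) / sqrt(denom[ok])
        out
      }
    },
    error = {
      e <- rowMeans(if (spec$error_mode == "squared") {
        (matrix(y, K, length(y), byrow = TRUE) - P)^2
      } else {
        abs(matrix(y, K, length(y), byrow = TRUE) - P)
      })
      1 / (e + 1)
    },
    xent = {
      Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
      J <- -(log(Pc) %*% y + log(1 - Pc) %*% (1 - y))
      as.numeric(1 / (1 + J))
    },
    stop("eval_fitness(): unknown fitness id", call. = FALSE)
  )
  if (!is.null(counter)) counter$n <- counter$n + K
  as.numeric(f)
}

#' Full metric report for one set of predicted probabilities
#'
#' Computes the six evaluation metrics: accuracy, F1, MCC, ROC-AUC,
#' false-negative rate, false-positive rate. ROC-AUC is computed from the
#' continuous probabilities by default; `roc = "hard"` ranks the rounded
#' labels instead.
#'
#' @param actual Binary labels.
#' @param probabilities Predicted class-1 probabilities.
#' @param roc `"prob"` (default) or `"hard"`.
#' @return Named list `acc`, `f1`, `mcc`, `roc_auc`, `fnr`, `fpr`.
#' @export
metric_report <- function(actual, probabilities, roc = c("prob", "hard")) {
  roc <- match.arg(roc)
  pred <- predict_class(probabilities)
  er <- error_rates(actual, pred)
  scores <- if (roc == "prob") probabilities else as.numeric(pred)
  list(
    acc = accuracy(actual, pred),
    f1 = f1_score(actual, pred),
    mcc = mcc(actual, pred),
    roc_auc = roc_auc(actual, scores),
    fnr = unname(er["fnr"]),
    fpr = unname(er["fpr"])
  )
}
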