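#' Logistic sigmoid
#'
#' Elementwise logistic function \eqn{\sigma(a) = 1 / (1 + e^{-a})}. The
#' output lies in the open interval (0, 1) and is strictly increasing.
#'
#' @param a Numeric vector, matrix, or scalar. Must be finite.
#' @return Object of the same shape as `a` with entries in (0, 1).
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(0.5)    # 0.6224593
#' @export
sigmoid <- function(a) {
  if (!is.numeric(a) || anyNA(a) || any(!is.finite(a))) {
    stop("sigmoid(): input must be finite numeric", call. = FALSE)
  }
  1 / (1 + exp(-a))
}

# Canonical parameter layout: theta[1] is the bias b, theta[-1] the feature
# weights w, so length(theta) = D = N + 1. A batch is a K x D matrix with one
# candidate per row. as_param_batch() normalises either form to a matrix.
as_param_batch <- function(theta) {
  if (is.matrix(theta)) theta else matrix(theta, nrow = 1L)
}

#' Predicted class-1 probabilities
#'
#' Computes \eqn{\sigma(w \cdot x_i + b)} for every instance and every
#' candidate parameter vector. Parameters use the bias-first layout:
#' `theta[1]` is the bias, the remaining `N` entries are feature weights.
#'
#' @param theta Numeric vector of length `N + 1`, or a `K x (N + 1)` matrix
#'   of `K` candidates (one per row).
#' @param X Numeric feature matrix, `M x N`, finite.
#' @return For a vector `theta`, a length-`M` probability vector; for a
#'   matrix, a `K x M` matrix whose `(k, i)` entry is the probability that
#'   instance `i` is class 1 under candidate `k`.
#' @export
predict_proba <- function(theta, X) {
  single <- !is.matrix(theta)
  W <- as_param_batch(theta)
  X <- as.matrix(X)
  if (ncol(W) != ncol(X) + 1L) {
    stop(sprintf(
      "predict_proba(): parameter length %d does not match N + 1 = %d",
      ncol(W), ncol(X) + 1L), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("predict_proba(): X must be finite", call. = FALSE)
  }
  b <- W[, 1L]
  w <- W[, -1L, drop = FALSE]
  # M x K linear predictor, transposed to K x M
  p <- t(sigmoid(sweep(X %*% t(w), 2L, b, "+")))
  if (single) drop(p) else p
}

#' Threshold probabilities to class labels
#'
#' Label 1 iff `p >= 0.5`, else 0 (ties at the 0.5 boundary go to class 1).
#'
#' @param p Numeric vector/matrix of probabilities in \[0, 1\].
#' @return Integer labels of the same shape, values in `{0, 1}`.
#' @export
predict_class <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("predict_class(): probabilities must lie in [0, 1]", call. = FALSE)
  }
  lab <- (p >= 0.5) * 1L
  storage.mode(lab) <- "integer"
  lab
}

#' Cross-entropy cost of a parameter vector
#'
#' The summed (not averaged) binary cross-entropy
#' \eqn{J = -\sum_i [y_i \log p_i + (1 - y_i) \log(1 - p_i)]}. Probabilities
#' are clipped into \eqn{[\epsilon, 1 - \epsilon]} before the logarithms so
#' the cost stays finite at saturated predictions.
#'
#' @param theta Parameter vector, bias first, length `N + 1`.
#' @param X Feature matrix `M x N`.
#' @param y Binary label vector of length `M`.
#' @param eps Clipping constant, default `1e-12`.
#' @return Non-negative scalar cost.
#' @export
cross_entropy_cost <- function(theta, X, y, eps = 1e-12) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("cross_entropy_cost(): empty dataset", call. = FALSE)
  check_binary(y, nrow(X), "y")
  p <- predict_proba(theta, X)
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

# shared validation: binary vector of given length
check_binary <- function(x, len = NULL, what = "labels") {
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("%s must be a binary (0/1) vector", what), call. = FALSE)
  }
  if (!is.null(len) && length(x) != len) {
    stop(sprintf("%s has length %d, expected %d", what, length(x), len),
         call. = FALSE)
  }
  invisible(x)
}

# round() in R is banker's rounding; the population-count arithmetic here
# needs half away from zero (0.5 -> 1).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
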