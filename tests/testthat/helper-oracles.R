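# Independent brute-force oracles used by the property and acceptance
# tests. These deliberately avoid the package's vectorised code paths.

# literal four-way enumeration of (actual, predicted) pairs
oracle_confusion <- function(actual, predicted) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(actual)) {
    if (actual[i] == 1 && predicted[i] == 1) tp <- tp + 1L
    else if (actual[i] == 0 && predicted[i] == 0) tn <- tn + 1L
    else if (actual[i] == 0 && predicted[i] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_metrics <- function(actual, predicted) {
  cc <- oracle_confusion(actual, predicted)
  with(cc, {
    m <- length(actual)
    denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    list(
      acc = (tp + tn) / m,
      f1 = if (tp == 0) 0 else {
        pr <- tp / (tp + fp); rc <- tp / (tp + fn)
        2 * pr * rc / (pr + rc)
      },
      mcc = if (denom == 0) 0 else
        (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom),
      fnr = if (tp + fn == 0) 0 else fn / (tp + fn),
      fpr = if (tn + fp == 0) 0 else fp / (tn + fp)
    )
  })
}

# O(M^2) pairwise AUC with half-credit ties
oracle_auc <- function(actual, scores) {
  pos <- which(actual == 1)
  neg <- which(actual == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  s / (length(pos) * length(neg))
}

# brute-force per-antibody selection: argmax over {parent, its clones},
# strict-improvement replacement, lowest clone index on ties
oracle_select <- function(W, fit, C, cfit, alpha) {
  P <- nrow(W)
  for (i in seq_len(P)) {
    rows <- ((i - 1) * alpha + 1):(i * alpha)
    best <- rows[1]
    for (r in rows) if (cfit[r] > cfit[best]) best <- r
    if (cfit[best] > fit[i]) {
      W[i, ] <- C[best, ]
      fit[i] <- cfit[best]
    }
  }
  list(W = W, fit = fit)
}

# exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments (midranks, so valid under ties); n must be small
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    w <- sum(r[signs])
    if (abs(w - mu) >= abs(W - mu) - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# deterministic separable dataset shared by convergence-style tests
separable_data <- function(n = 200, d = 2, seed = 7) {
  make_logistic_data(n, d, c(-3, 4, 2)[seq_len(d + 1)],
                     noise = "none", seed = seed, margin = 0.1)
}

train_accuracy <- function(model, ds) {
  accuracy(ds$y, predict_class(predict_proba(model$theta, ds$X)))
}
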