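#' Generate a dataset with known logistic structure
#'
#' Features are drawn uniformly on \[0, 1\]^d, mirroring the post-min-max
#' scale the optimizers see on real tables. With `noise = "bernoulli"`,
#' labels are drawn `y ~ Bernoulli(sigma(b + w . x))`; with
#' `noise = "none"`, `y = 1(sigma >= 0.5)`, which makes `true_theta` an
#' exact separator of the emitted data. An optional `margin` discards
#' instances with `|sigma - 0.5| < margin`, guaranteeing a fat separating
#' band for convergence tests. Generation retries (up to 100 times) until
#' both classes are present.
#'
#' @param n Instance count (>= 2).
#' @param d Feature count (>= 1).
#' @param true_theta Generating parameter vector, bias first, length `d + 1`.
#' @param noise `"bernoulli"` (default) or `"none"`.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param margin Minimum `|sigma - 0.5|` kept, in \[0, 0.5); default 0.
#' @return An [as_dataset()] object with a `"true_theta"` attribute.
#' @export
make_logistic_data <- function(n, d, true_theta,
                               noise = c("bernoulli", "none"),
                               seed = 1L, margin = 0) {
  noise <- match.arg(noise)
  if (n < 2 || d < 1) stop("make_logistic_data(): need n >= 2, d >= 1", call. = FALSE)
  if (length(true_theta) != d + 1L) {
    stop("make_logistic_data(): true_theta must have length d + 1", call. = FALSE)
  }
  if (margin < 0 || margin >= 0.5) {
    stop("make_logistic_data(): margin in [0, 0.5) required", call. = FALSE)
  }
  with_seed(seed, function() {
    for (attempt in seq_len(100L)) {
      X <- matrix(stats::runif(n * d), n, d)
      p <- sigmoid(true_theta[1L] + as.vector(X %*% true_theta[-1L]))
      if (margin > 0) {
        keep <- abs(p - 0.5) >= margin
        # top up rejected rows until n survivors
        while (sum(keep) < n) {
          m <- n - sum(keep)
          Xe <- matrix(stats::runif(4L * m * d), ncol = d)
          pe <- sigmoid(true_theta[1L] + as.vector(Xe %*% true_theta[-1L]))
          ok <- abs(pe - 0.5) >= margin
          X <- rbind(X[keep, , drop = FALSE], Xe[ok, , drop = FALSE])
          p <- c(p[keep], pe[ok])
          keep <- rep(TRUE, length(p))
        }
        X <- X[seq_len(n), , drop = FALSE]
        p <- p[seq_len(n)]
      }
      y <- if (noise == "bernoulli") {
        as.numeric(stats::runif(n) < p)
      } else {
        as.numeric(p >= 0.5)
      }
      if (length(unique(y)) == 2L) {
        ds <- as_dataset(X, y, paste0("x", seq_len(d)), name = "synthetic")
        attr(ds, "true_theta") <- true_theta
        return(ds)
      }
    }
    stop("make_logistic_data(): could not produce both classes in 100 attempts",
         call. = FALSE)
  })
}

#' Deterministic 8-instance toy fixture
#'
#' A hard-coded 8 x 2 table with both classes, plus the metric report of a
#' fixed parameter vector `theta = (-0.6, 1.2, 0.4)`. The stored expected
#' values were pre-computed by brute-force confusion-matrix enumeration
#' (tp = 4, tn = 1, fp = 2, fn = 1) and pairwise ROC comparison, and are
#' byte-stable across runs.
#'
#' @return List with fields `dataset` (an `lr_dataset`), `theta`, and
#'   `expected` (acc, f1, mcc, roc_auc, fnr, fpr).
#' @export
toy_fixture <- function() {
  X <- matrix(c(0.10, 0.20,
                0.90, 0.80,
                0.30, 0.70,
                0.80, 0.20,
                0.50, 0.50,
                0.95, 0.10,
                0.05, 0.95,
                0.60, 0.90), ncol = 2L, byrow = TRUE)
  y <- c(0, 1, 1, 0, 1, 0, 1, 1)
  list(
    dataset = as_dataset(X, y, c("x1", "x2"), name = "toy"),
    theta = c(-0.6, 1.2, 0.4),
    expected = list(
      acc = 0.625,
      f1 = 8 / 11,                    # precision 4/6, recall 4/5
      mcc = 2 / sqrt(180),            # (4*1 - 2*1) / sqrt(6*5*3*2)
      roc_auc = 8 / 15,               # 8 of the 15 positive-negative pairs won
      fnr = 1 / 5,
      fpr = 2 / 3
    )
  )
}

#' Write a dataset as delimited text in the whitespace heart-table dialect
#'
#' Serialises features followed by the 1/2 label column so the file can be
#' re-read with `load_dataset(dialect = "statlog")`, letting the whole
#' pipeline run end-to-end offline. Only 13-feature tables round-trip
#' through the statlog reader; other widths are still written (features +
#' label) for generic use.
#'
#' @param dataset An `lr_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_statlog <- function(dataset, path) {
  stopifnot(inherits(dataset, "lr_dataset"))
  tab <- cbind(dataset$X, dataset$y + 1)
  utils::write.table(tab, path, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
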