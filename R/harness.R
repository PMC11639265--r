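#' Cross-validated evaluation of one trainer on one dataset
#'
#' For each fold, the scaler is fitted on the training rows only and
#' applied to both partitions, the model is trained on the scaled training
#' rows, and the six metrics (accuracy, F1, MCC, ROC-AUC, FNR, FPR) are
#' computed on the held-out rows. Per-fold trained parameter vectors are
#' retained for feature-weight export. The per-fold training seed is
#' `seed * 1000 + fold` so folds are independent but reproducible.
#'
#' @param dataset An `lr_dataset`.
#' @param algorithm `"csa_de_lr"`, `"csa_lr"`, or `"de_lr"`.
#' @param config An [optimizer_config()] (its `seed` field is overridden
#'   per fold as described above).
#' @param spec A [fitness_spec()].
#' @param k Fold count (default 10).
#' @param seed Split/training seed.
#' @param scale `"minmax"` (default) or `"zscore"`.
#' @param stratified Stratify the fold split (default `TRUE`).
#' @param roc ROC-AUC input: `"prob"` (default) or `"hard"` labels.
#' @return Object of class `cv_report`: per-fold metric data frame `folds`,
#'   `mean` and `sd` (population formula, divisor `k`) per metric, the
#'   per-fold `models`, and identifiers.
#' @export
cross_validate <- function(dataset, algorithm = "csa_de_lr",
                           config = optimizer_config(),
                           spec = fitness_spec("f1"),
                           k = 10, seed = 1L,
                           scale = c("minmax", "zscore"),
                           stratified = TRUE, roc = c("prob", "hard")) {
  stopifnot(inherits(dataset, "lr_dataset"))
  scale <- match.arg(scale)
  roc <- match.arg(roc)
  folds <- kfold_split(dataset, k = k, seed = seed, stratified = stratified)
  metric_names <- c("acc", "f1", "mcc", "roc_auc", "fnr", "fpr")
  rows <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(dataset$X)), test_idx)
    sc <- fit_scaler(dataset$X[train_idx, , drop = FALSE], scale)
    Xtr <- apply_scaler(sc, dataset$X[train_idx, , drop = FALSE])
    Xte <- apply_scaler(sc, dataset$X[test_idx, , drop = FALSE])
    cfg <- config
    cfg$seed <- as.integer(seed * 1000L + f)
    model <- fit_model(Xtr, dataset$y[train_idx], cfg, spec, algorithm)
    p <- predict_proba(model$theta, Xte)
    rep <- metric_report(dataset$y[test_idx], p, roc = roc)
    rows[[f]] <- as.data.frame(rep[metric_names])
    models[[f]] <- model
  }
  folds_df <- do.call(rbind, rows)
  rownames(folds_df) <- NULL
  structure(list(
    folds = folds_df,
    mean = colMeans(folds_df),
    sd = apply(folds_df, 2L, function(v) sqrt(mean((v - mean(v))^2))),
    models = models, k = k, dataset = dataset$name,
    algorithm = algorithm, fitness = spec$id, seed = seed
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s on '%s', %d-fold, fitness %s>\n",
              x$algorithm, x$dataset, x$k, x$fitness))
  print(format_cv_report(x))
  invisible(x)
}

#' Format a CV report in the benchmark-table style
#'
#' Accuracy, F1, MCC and ROC-AUC are reported as percentages to two
#' decimals; FNR and FPR as raw rates to three decimals; each as
#' `mean +/- sd`.
#'
#' @param report A [cross_validate()] result.
#' @return Named character vector, one entry per metric.
#' @export
format_cv_report <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  pct <- c("acc", "f1", "mcc", "roc_auc")
  out <- character(0)
  for (m in names(report$mean)) {
    out[m] <- if (m %in% pct) {
      sprintf("%.2f ± %.3f", 100 * report$mean[[m]], report$sd[[m]])
    } else {
      sprintf("%.3f ± %.3f", report$mean[[m]], report$sd[[m]])
    }
  }
  out
}

#' Per-feature mean weights across folds
#'
#' Averages the feature weights of the per-fold trained models; the bias
#' is excluded from the per-feature table and reported separately.
#'
#' @param models List of `trained_model`s (or bare parameter vectors) of
#'   equal length.
#' @param feature_names Names for the `D - 1` feature coordinates.
#' @return List with `mean` (named per-feature means), `bias_mean`,
#'   `table` (fold x feature data frame), and `bias` (per-fold vector).
#' @export
mean_feature_weights <- function(models, feature_names = NULL) {
  thetas <- lapply(models, function(m) {
    if (inherits(m, "trained_model")) m$theta else as.numeric(m)
  })
  D <- unique(vapply(thetas, length, integer(1)))
  if (length(D) != 1L) {
    stop("mean_feature_weights(): inconsistent parameter lengths", call. = FALSE)
  }
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(D - 1L))
  if (length(feature_names) != D - 1L) {
    stop("mean_feature_weights(): feature_names must have length D - 1", call. = FALSE)
  }
  mat <- do.call(rbind, thetas)
  tab <- as.data.frame(mat[, -1L, drop = FALSE])
  names(tab) <- feature_names
  list(mean = colMeans(tab), bias_mean = mean(mat[, 1L]),
       table = tab, bias = mat[, 1L])
}

#' Default hyperparameter search space
#'
#' The tuning ranges for each trainer: `lb` in \[-64, -16\], `ub` in
#' \[16, 64\], `P` in \[10, 80\] (integer), `alpha` in \[2, 6\] (integer),
#' `B` in \[0.05, 0.2\], `sf` in \[0.01, 2\], `cr` in \[0.01, 1\]. Fields
#' not tuned by an algorithm are omitted.
#'
#' @param algorithm Trainer key.
#' @return Named list of `list(low, high, integer)` entries.
#' @export
default_search_space <- function(algorithm = c("csa_de_lr", "csa_lr", "de_lr")) {
  algorithm <- match.arg(algorithm)
  full <- list(
    lb = list(low = -64, high = -16, integer = FALSE),
    ub = list(low = 16, high = 64, integer = FALSE),
    P = list(low = 10, high = 80, integer = TRUE),
    alpha = list(low = 2, high = 6, integer = TRUE),
    B = list(low = 0.05, high = 0.2, integer = FALSE),
    sf = list(low = 0.01, high = 2, integer = FALSE),
    cr = list(low = 0.01, high = 1, integer = FALSE)
  )
  keep <- switch(algorithm,
    csa_de_lr = c("lb", "ub", "P", "alpha", "B", "sf", "cr"),
    csa_lr = c("lb", "ub", "P", "alpha", "B"),
    de_lr = c("lb", "ub", "P", "sf", "cr"))
  full[keep]
}

sample_space <- function(space) {
  out <- list()
  for (nm in names(space)) {
    s <- space[[nm]]
    out[[nm]] <- if (isTRUE(s$integer)) {
      s$low + sample.int(s$high - s$low + 1L, 1L) - 1L   # inclusive uniform
    } else {
      stats::runif(1L, s$low, s$high)
    }
  }
  out
}

#' Seeded random-search hyperparameter tuning
#'
#' Samples configurations uniformly from the search space (integers
#' inclusive, reals uniform), scores each by the mean cross-validated value
#' of the chosen metric, and returns the argmax configuration together
#' with the full trial log. This is a deliberate seeded-random-search
#' replacement for Bayesian/TPE tuners.
#'
#' @param dataset An `lr_dataset`.
#' @param algorithm Trainer key.
#' @param space Search space as in [default_search_space()].
#' @param iterations Number of sampled configurations (>= 1).
#' @param seed Sampling seed.
#' @param spec Fitness used for training during scoring.
#' @param metric Objective metric, default `"acc"`.
#' @param k Fold count of the scoring CV.
#' @param MEN Evaluation budget for each trained model.
#' @return List `best_config` ([optimizer_config()]), `best_score`, and
#'   `trials` (data frame of sampled values and scores).
#' @export
random_search_tune <- function(dataset, algorithm = "csa_de_lr",
                               space = default_search_space(algorithm),
                               iterations = 10, seed = 1L,
                               spec = fitness_spec("f1"),
                               metric = "acc", k = 10, MEN = 30000) {
  if (length(space) == 0L) stop("random_search_tune(): empty space", call. = FALSE)
  if (iterations < 1L) stop("random_search_tune(): iterations >= 1 required", call. = FALSE)
  samples <- with_seed(seed, function() {
    lapply(seq_len(iterations), function(i) sample_space(space))
  })
  scores <- numeric(iterations)
  for (i in seq_len(iterations)) {
    cfg <- do.call(optimizer_config,
                   c(samples[[i]], list(MEN = MEN, seed = seed)))
    cv <- cross_validate(dataset, algorithm, cfg, spec, k = k, seed = seed)
    scores[i] <- cv$mean[[metric]]
  }
  trials <- cbind(as.data.frame(do.call(rbind, lapply(samples, as.data.frame))),
                  score = scores)
  best <- which.max(scores)
  list(
    best_config = do.call(optimizer_config,
                          c(samples[[best]], list(MEN = MEN, seed = seed))),
    best_score = scores[best],
    trials = trials
  )
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are removed; absolute differences are midranked. For
#' `n <= 25` remaining pairs the two-sided p-value comes from the exact
#' null distribution of the positive-rank sum, computed by dynamic
#' programming over the (doubled, hence integer) rank values — valid under
#' tied ranks. For larger `n` a normal approximation with continuity
#' correction and the usual tie correction is used.
#'
#' @param a,b Paired numeric vectors of equal length >= 5 with at least
#'   one nonzero difference.
#' @return List `p_value` (in (0, 1\]), `statistic` (positive-rank sum
#'   `W`), `n` (pairs after zero removal), `exact` (logical).
#' @export
wilcoxon_compare <- function(a, b) {
  if (length(a) != length(b) || length(a) < 5L) {
    stop("wilcoxon_compare(): need paired samples of equal length >= 5", call. = FALSE)
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("wilcoxon_compare(): all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))      # doubled midranks are integers
    total <- sum(r2)
    # counts[s + 1] = number of sign assignments with doubled rank sum s
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (v in r2) {
      shifted <- c(rep(0, v), counts[seq_len(length(counts) - v)])
      counts <- counts + shifted
    }
    w2 <- round(2 * W)
    mu <- total / 2
    extreme <- abs(seq(0L, total) - mu) >= abs(w2 - mu) - 1e-9
    p <- sum(counts[extreme]) / 2^n
    list(p_value = min(1, p), statistic = W, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    list(p_value = min(1, 2 * stats::pnorm(-abs(z))), statistic = W,
         n = n, exact = FALSE)
  }
}

#' Run a full comparison experiment and write its report files
#'
#' Executes [cross_validate()] for every algorithm x dataset x seed in the
#' plan, writes a formatted metric table (CSV) per dataset, per-fold
#' feature-weight CSVs, a machine-readable JSON report, and — when two or
#' more algorithms are run over five or more seeds — a Wilcoxon p-value
#' matrix comparing the first algorithm against the rest, paired by seed,
#' for accuracy, F1 and MCC.
#'
#' @param plan List with fields: `datasets` (named list of `lr_dataset`),
#'   `algorithms` (character), `seeds` (integer vector), and optionally
#'   `config` (an [optimizer_config()] or `"preset"` to use
#'   [preset_config()] per dataset), `fitness`, `error_mode`, `k`,
#'   `scale`, `MEN`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the report list also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_experiment <- function(plan, out_dir) {
  stopifnot(is.list(plan), length(plan$datasets) >= 1L,
            length(plan$algorithms) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- if (is.null(plan$seeds)) 1L else as.integer(plan$seeds)
  k <- if (is.null(plan$k)) 10L else plan$k
  spec <- fitness_spec(if (is.null(plan$fitness)) "f1" else plan$fitness,
                       if (is.null(plan$error_mode)) "squared" else plan$error_mode)
  report <- list()
  for (ds_name in names(plan$datasets)) {
    ds <- plan$datasets[[ds_name]]
    scale <- if (!is.null(plan$scale)) plan$scale
             else if (ds_name == "wbcd") "zscore" else "minmax"
    per_algo <- list()
    table_rows <- list()
    for (algo in plan$algorithms) {
      cfg <- if (is.null(plan$config)) optimizer_config()
             else if (identical(plan$config, "preset")) {
               preset_config(ds_name, algo,
                             MEN = if (is.null(plan$MEN)) 30000 else plan$MEN)
             } else plan$config
      runs <- lapply(seeds, function(s) {
        cross_validate(ds, algo, cfg, spec, k = k, seed = s, scale = scale)
      })
      means <- do.call(rbind, lapply(runs, function(r) r$mean))
      per_algo[[algo]] <- list(
        per_seed_mean = as.data.frame(means),
        folds = lapply(runs, function(r) r$folds)
      )
      table_rows[[algo]] <- format_cv_report(runs[[1L]])
      wts <- mean_feature_weights(runs[[1L]]$models, ds$feature_names)
      utils::write.csv(
        cbind(fold = seq_len(k), bias = wts$bias, wts$table),
        file.path(out_dir, sprintf("weights_%s_%s.csv", ds_name, algo)),
        row.names = FALSE)
    }
    tab <- do.call(rbind, table_rows)
    utils::write.csv(data.frame(method = rownames(tab), tab,
                                check.names = FALSE),
                     file.path(out_dir, sprintf("metrics_%s.csv", ds_name)),
                     row.names = FALSE)
    if (length(plan$algorithms) >= 2L && length(seeds) >= 5L) {
      ref <- plan$algorithms[1L]
      wil <- list()
      for (algo in setdiff(plan$algorithms, ref)) {
        wil[[algo]] <- lapply(c(acc = "acc", f1 = "f1", mcc = "mcc"),
          function(m) {
            wilcoxon_compare(per_algo[[ref]]$per_seed_mean[[m]],
                             per_algo[[algo]]$per_seed_mean[[m]])$p_value
          })
      }
      per_algo$wilcoxon_vs_first <- wil
    }
    report[[ds_name]] <- per_algo
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
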