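# UCI column names referenced by the feature-weight analyses.
.heart_features <- c("age", "sex", "cp", "trestbps", "chol", "fbs",
                     "restecg", "thalach", "exang", "oldpeak", "slope",
                     "ca", "thal")
.wbco_features <- c("clump_thickness", "cell_size_uniformity",
                    "cell_shape_uniformity", "marginal_adhesion",
                    "epithelial_cell_size", "bare_nuclei",
                    "bland_chromatin", "normal_nucleoli", "mitoses")
.wbcd_features <- as.vector(t(outer(
  c("mean", "se", "worst"),
  c("radius", "texture", "perimeter", "area", "smoothness", "compactness",
    "concavity", "concave_points", "symmetry", "fractal_dimension"),
  paste, sep = "_")))

#' Construct a binary-classification dataset
#'
#' @param X Numeric feature matrix `M x N` without missing values.
#' @param y Binary (0/1) labels, both classes present.
#' @param feature_names Character vector of length `N`.
#' @param name Dataset identifier.
#' @param dropped_rows Count of rows removed for missing values.
#' @return Object of class `lr_dataset`.
#' @export
as_dataset <- function(X, y, feature_names = colnames(X),
                       name = "dataset", dropped_rows = 0L) {
  X <- as.matrix(X)
  if (is.null(feature_names)) {
    feature_names <- paste0("x", seq_len(ncol(X)))
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("as_dataset(): X must be finite with no missing values", call. = FALSE)
  }
  check_binary(y, nrow(X), "y")
  if (nrow(X) < 2L || length(unique(y)) < 2L) {
    stop("as_dataset(): need M >= 2 with both classes present", call. = FALSE)
  }
  colnames(X) <- feature_names
  structure(list(X = X, y = as.numeric(y),
                 feature_names = feature_names, name = name,
                 dropped_rows = as.integer(dropped_rows)),
            class = "lr_dataset")
}

#' @export
print.lr_dataset <- function(x, ...) {
  cat(sprintf("<lr_dataset '%s': %d instances x %d features, %d positive, %d rows dropped>\n",
              x$name, nrow(x$X), ncol(x$X), sum(x$y == 1), x$dropped_rows))
  invisible(x)
}

#' Load a delimited clinical table in one of the four UCI dialects
#'
#' Dialects: `cleveland` -- comma-separated, 14 columns, last column the
#' 0-4 disease stage (binarized 0 vs 1-4), `'?'` markers possible in any
#' field; `statlog` -- whitespace-separated, 14 columns, labels 1 (absent)
#' / 2 (present); `wbco` -- comma-separated, 11 columns with a leading
#' sample ID (dropped), classes 2 (benign) / 4 (malignant); `wbcd` --
#' comma-separated, 32 columns with leading ID (dropped) and diagnosis
#' `B`/`M` in column 2. Rows containing the `'?'` missing marker in any
#' field are removed (listwise) and counted.
#'
#' @param source Path to the delimited text file.
#' @param dialect One of `"cleveland"`, `"statlog"`, `"wbco"`, `"wbcd"`.
#' @return An [as_dataset()] object; `$dropped_rows` holds the number of
#'   removed rows.
#' @export
load_dataset <- function(source,
                         dialect = c("cleveland", "statlog", "wbco", "wbcd")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "statlog") "" else ","
  raw <- utils::read.table(source, sep = sep, header = FALSE,
                           colClasses = "character",
                           strip.white = TRUE, stringsAsFactors = FALSE)
  ncols <- c(cleveland = 14L, statlog = 14L, wbco = 11L, wbcd = 32L)[[dialect]]
  if (ncol(raw) != ncols) {
    stop(sprintf("load_dataset(): %s dialect expects %d columns, found %d",
                 dialect, ncols, ncol(raw)), call. = FALSE)
  }
  miss <- apply(raw == "?", 1L, any)
  dropped <- sum(miss)
  raw <- raw[!miss, , drop = FALSE]

  if (dialect == "cleveland") {
    feat_cols <- 1:13; target_col <- 14L; names <- .heart_features
  } else if (dialect == "statlog") {
    feat_cols <- 1:13; target_col <- 14L; names <- .heart_features
  } else if (dialect == "wbco") {
    feat_cols <- 2:10; target_col <- 11L; names <- .wbco_features
  } else {
    feat_cols <- 3:32; target_col <- 2L; names <- .wbcd_features
  }

  if (dialect == "wbcd") {
    lab <- raw[[target_col]]
    bad <- !lab %in% c("B", "M")
    if (any(bad)) {
      stop(sprintf("load_dataset(): non-B/M diagnosis at line %d",
                   which(bad)[1L]), call. = FALSE)
    }
    y <- as.numeric(lab == "M")
  } else {
    tv <- suppressWarnings(as.numeric(raw[[target_col]]))
    if (anyNA(tv)) {
      stop(sprintf("load_dataset(): non-numeric target at line %d",
                   which(is.na(tv))[1L]), call. = FALSE)
    }
    y <- switch(dialect,
      cleveland = as.numeric(tv > 0),           # 0 healthy vs stages 1-4
      statlog = tv - 1,                         # 1 -> 0, 2 -> 1
      wbco = as.numeric(tv == 4))               # 2 benign, 4 malignant
  }

  X <- matrix(NA_real_, nrow(raw), length(feat_cols))
  for (k in seq_along(feat_cols)) {
    v <- suppressWarnings(as.numeric(raw[[feat_cols[k]]]))
    if (anyNA(v)) {
      stop(sprintf("load_dataset(): non-numeric value in feature '%s' at line %d",
                   names[k], which(is.na(v))[1L]), call. = FALSE)
    }
    X[, k] <- v
  }
  as_dataset(X, y, names, name = dialect, dropped_rows = dropped)
}

#' Fit per-feature scaling statistics on training rows
#'
#' `minmax` maps the training rows of each feature onto \[0, 1\]; `zscore`
#' centers by the training mean and divides by the population standard
#' deviation (divisor `n`). Constant features are mapped to 0 (with a
#' warning under `zscore`). Statistics learned here are reused on test
#' rows, which may therefore fall outside \[0, 1\].
#'
#' @param X Training feature matrix.
#' @param method `"minmax"` or `"zscore"`.
#' @return Object of class `scaler_params`.
#' @export
fit_scaler <- function(X, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("fit_scaler(): empty training matrix", call. = FALSE)
  if (method == "minmax") {
    center <- apply(X, 2L, min)
    scale <- apply(X, 2L, max) - center
  } else {
    center <- colMeans(X)
    scale <- sqrt(colMeans(sweep(X, 2L, center)^2))  # population sd
    if (any(scale == 0)) {
      warning("fit_scaler(): constant feature(s) under zscore mapped to 0")
    }
  }
  degenerate <- scale == 0
  scale[degenerate] <- 1                # transformed value becomes 0
  structure(list(method = method, center = center, scale = scale,
                 degenerate = degenerate),
            class = "scaler_params")
}

#' Apply fitted scaling statistics
#'
#' @param params A [fit_scaler()] result.
#' @param X Feature matrix to transform (train or test rows).
#' @return Scaled matrix of the same shape.
#' @export
apply_scaler <- function(params, X) {
  stopifnot(inherits(params, "scaler_params"))
  X <- as.matrix(X)
  if (ncol(X) != length(params$center)) {
    stop("apply_scaler(): feature count mismatch", call. = FALSE)
  }
  out <- sweep(sweep(X, 2L, params$center), 2L, params$scale, "/")
  out[, params$degenerate] <- 0
  out
}

#' k-fold split plan
#'
#' Produces `k` disjoint index sets covering all instances with sizes
#' differing by at most one. Stratified splitting (the default) additionally
#' keeps per-class proportions within one instance per fold. The assignment
#' is shuffled by `seed` and reproducible.
#'
#' @param dataset An `lr_dataset`, or a label vector.
#' @param k Number of folds, `2 <= k <= M`.
#' @param seed Integer shuffle seed.
#' @param stratified Preserve class proportions per fold (default `TRUE`).
#' @return List of `k` integer index vectors (1-based).
#' @export
kfold_split <- function(dataset, k = 10, seed = 1L, stratified = TRUE) {
  y <- if (inherits(dataset, "lr_dataset")) dataset$y else dataset
  M <- length(y)
  if (k < 2 || k > M) stop("kfold_split(): need 2 <= k <= M", call. = FALSE)
  with_seed(seed, function() {
    if (stratified) {
      ord <- unlist(lapply(sort(unique(y)), function(cl) {
        idx <- which(y == cl)
        idx[sample.int(length(idx))]
      }), use.names = FALSE)
    } else {
      ord <- sample.int(M)
    }
    # cyclic fold labels along the (class-blocked) shuffled order keep both
    # overall and per-class fold sizes within 1
    fold <- rep_len(seq_len(k), M)
    lapply(unname(split(ord, fold)), unname)
  })
}

# feature-drop presets identified by the cross-validated weight analysis
.drop_presets <- list(
  statlog_fs = "restecg",
  cleveland_fs = c("trestbps", "fbs", "restecg")
)

#' Remove named features from a dataset
#'
#' Preset names `"statlog_fs"` (drops `restecg`) and `"cleveland_fs"`
#' (drops `trestbps`, `fbs`, `restecg`) expand to the feature sets whose
#' fold-to-fold weight instability motivated their removal.
#'
#' @param dataset An `lr_dataset`.
#' @param names Character vector of feature names, or a preset name.
#' @return A new `lr_dataset` with the remaining columns in order.
#' @export
drop_features <- function(dataset, names) {
  stopifnot(inherits(dataset, "lr_dataset"))
  if (length(names) == 1L && names %in% names(.drop_presets)) {
    names <- .drop_presets[[names]]
  }
  unknown <- setdiff(names, dataset$feature_names)
  if (length(unknown)) {
    stop(sprintf("drop_features(): unknown feature(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep <- !(dataset$feature_names %in% names)
  as_dataset(dataset$X[, keep, drop = FALSE], dataset$y,
             dataset$feature_names[keep], dataset$name,
             dataset$dropped_rows)
}
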