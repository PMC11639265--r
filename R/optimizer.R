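#' Optimizer configuration
#'
#' Box bounds and population hyperparameters shared by all three trainers.
#' `alpha` and `B` are ignored by the plain-DE trainer; `sf` and `cr` are
#' ignored by the classic clonal-selection trainer.
#'
#' @param lb,ub Lower/upper box bound applied to every parameter coordinate.
#' @param P Antibody (population) count; the DE step requires `P >= 4`.
#' @param alpha Clones per antibody (>= 1).
#' @param B Receptor-editing fraction in \[0, 1): each iteration the worst
#'   `round(P * B)` antibodies (half-up rounding) are replaced by fresh
#'   random draws.
#' @param sf DE scaling factor (> 0).
#' @param cr DE crossover rate in \[0, 1\].
#' @param MEN Maximum evaluation number: the fitness-evaluation budget that
#'   terminates the training loop (checked at the top of each iteration).
#' @param seed Integer RNG seed; every source of randomness in a fit call
#'   derives from it.
#' @return Object of class `optimizer_config`.
#' @export
optimizer_config <- function(lb = -16, ub = 16, P = 40, alpha = 3, B = 0.1,
                             sf = 0.5, cr = 0.9, MEN = 30000, seed = 1L) {
  if (!is.numeric(lb) || !is.numeric(ub) || lb >= ub) {
    stop("optimizer_config(): need lb < ub", call. = FALSE)
  }
  if (P < 4) stop("optimizer_config(): P >= 4 required (DE needs 3 distinct neighbours)", call. = FALSE)
  if (alpha < 1) stop("optimizer_config(): alpha >= 1 required", call. = FALSE)
  if (B < 0 || B >= 1 || round_half_up(P * B) >= P) {
    stop("optimizer_config(): need 0 <= B < 1 with round(P * B) < P", call. = FALSE)
  }
  if (sf <= 0) stop("optimizer_config(): sf > 0 required", call. = FALSE)
  if (cr < 0 || cr > 1) stop("optimizer_config(): cr in [0, 1] required", call. = FALSE)
  if (MEN < 0) stop("optimizer_config(): MEN >= 0 required", call. = FALSE)
  structure(list(lb = lb, ub = ub, P = as.integer(P),
                 alpha = as.integer(alpha), B = B, sf = sf, cr = cr,
                 MEN = as.integer(MEN), seed = as.integer(seed)),
            class = "optimizer_config")
}

# Tuned "Best" hyperparameter columns for the four benchmark datasets.
.table1_presets <- list(
  csa_de_lr = list(
    statlog   = list(lb = -48.353, ub = 19.487, P = 78L, alpha = 4L, B = 0.198, sf = 0.670, cr = 0.577),
    cleveland = list(lb = -27.010, ub = 24.245, P = 27L, alpha = 4L, B = 0.165, sf = 0.070, cr = 0.554),
    wbcd      = list(lb = -36.035, ub = 29.282, P = 37L, alpha = 3L, B = 0.132, sf = 0.167, cr = 0.333),
    wbco      = list(lb = -63.765, ub = 32.241, P = 10L, alpha = 5L, B = 0.053, sf = 1.610, cr = 0.958)
  ),
  csa_lr = list(
    statlog   = list(lb = -60.839, ub = 53.250, P = 74L, alpha = 4L, B = 0.050),
    cleveland = list(lb = -47.767, ub = 43.126, P = 61L, alpha = 3L, B = 0.162),
    wbcd      = list(lb = -44.305, ub = 45.543, P = 73L, alpha = 4L, B = 0.104),
    wbco      = list(lb = -61.344, ub = 27.328, P = 20L, alpha = 5L, B = 0.194)
  ),
  de_lr = list(
    statlog   = list(lb = -55.968, ub = 22.412, P = 53L, sf = 0.940, cr = 0.755),
    cleveland = list(lb = -34.463, ub = 22.809, P = 29L, sf = 1.790, cr = 0.432),
    wbcd      = list(lb = -53.381, ub = 38.460, P = 70L, sf = 0.116, cr = 0.651),
    wbco      = list(lb = -59.298, ub = 53.334, P = 50L, sf = 0.257, cr = 0.884)
  )
)

#' Named hyperparameter presets
#'
#' The tuned "best" hyperparameters for each algorithm on the four
#' benchmark datasets (Cleveland and Statlog heart disease, Wisconsin
#' breast cancer original/diagnostic). Fields an algorithm does not use
#' keep the [optimizer_config()] defaults.
#'
#' @param dataset One of `"statlog"`, `"cleveland"`, `"wbcd"`, `"wbco"`.
#' @param algorithm One of `"csa_de_lr"`, `"csa_lr"`, `"de_lr"`.
#' @param MEN,seed Budget and seed (not part of the tuned presets).
#' @return An [optimizer_config()].
#' @export
preset_config <- function(dataset = c("statlog", "cleveland", "wbcd", "wbco"),
                          algorithm = c("csa_de_lr", "csa_lr", "de_lr"),
                          MEN = 30000, seed = 1L) {
  dataset <- match.arg(dataset)
  algorithm <- match.arg(algorithm)
  p <- .table1_presets[[algorithm]][[dataset]]
  args <- utils::modifyList(list(MEN = MEN, seed = seed), p)
  do.call(optimizer_config, args)
}

#' Random antibody initialization
#'
#' Draws a `count x D` matrix with entries `lb + u * (ub - lb)`,
#' `u ~ Uniform[0, 1)`, using the current RNG state.
#'
#' @param count Number of antibodies (rows).
#' @param D Parameter dimension (bias + weights).
#' @param lb,ub Box bounds, `lb < ub`.
#' @return `count x D` numeric matrix with entries in `[lb, ub)`.
#' @export
create_antibodies <- function(count, D, lb, ub) {
  if (lb >= ub) stop("create_antibodies(): need lb < ub", call. = FALSE)
  if (count < 1 || D < 1) stop("create_antibodies(): invalid shape", call. = FALSE)
  matrix(lb + stats::runif(count * D) * (ub - lb), nrow = count, ncol = D)
}

#' Clone each antibody alpha times
#'
#' Row `k` of the clone matrix is a copy of antibody `ceiling(k / alpha)`,
#' so clones of antibody `i` occupy the contiguous block
#' `(i-1)*alpha + 1 .. i*alpha`, giving `P * alpha` rows in total.
#'
#' @param W `P x D` antibody matrix.
#' @param alpha Clones per antibody (>= 1).
#' @return `(P * alpha) x D` clone matrix.
#' @export
clone_antibodies <- function(W, alpha) {
  if (alpha < 1) stop("clone_antibodies(): alpha >= 1 required", call. = FALSE)
  W[rep(seq_len(nrow(W)), each = alpha), , drop = FALSE]
}

#' DE/rand/1/bin local search over the clone pool
#'
#' For each clone (owner antibody `j`), three distinct antibodies other
#' than `j` are chosen without replacement and one random clone of each is
#' used as a donor. A trial vector `donor1 + sf * (donor3 - donor2)`
#' replaces the clone's coordinates wherever a per-coordinate uniform draw
#' satisfies `u <= cr`; replaced coordinates are clipped into `[lb, ub]`.
#' There is no forced crossover coordinate, so a clone can survive
#' unchanged. Mutation is applied in place, sequentially, so later clones
#' may draw already-mutated donors.
#'
#' Per clone the RNG is consumed in a fixed order: 3 donor antibodies,
#' 3 clone offsets, D crossover uniforms.
#'
#' @param C `(P * alpha) x D` clone matrix.
#' @param P,alpha Population shape of `C`.
#' @param sf,cr,lb,ub DE scaling factor, crossover rate, and box bounds.
#' @return The mutated clone matrix.
#' @export
de_local_search <- function(C, P, alpha, sf, cr, lb, ub) {
  if (P < 4) stop("de_local_search(): P >= 4 required", call. = FALSE)
  D <- ncol(C)
  for (i in seq_len(P * alpha)) {
    j <- (i - 1L) %/% alpha + 1L
    inds <- seq_len(P)[-j]
    donors <- inds[sample.int(length(inds), 3L)]
    offsets <- sample.int(alpha, 3L, replace = TRUE) - 1L
    pars <- (donors - 1L) * alpha + offsets + 1L
    arr <- C[pars[1L], ] + sf * (C[pars[3L], ] - C[pars[2L], ])
    u <- stats::runif(D)
    rho <- u <= cr
    if (any(rho)) {
      vec <- arr[rho]
      vec[vec < lb] <- lb
      vec[vec > ub] <- ub
      C[i, rho] <- vec
    }
  }
  C
}

#' Greedy per-antibody clone selection
#'
#' Each antibody is replaced by its highest-fitness clone (lowest index on
#' ties) iff that clone is strictly fitter; ties keep the parent.
#'
#' @param W `P x D` antibody matrix with fitness vector `fit`.
#' @param fit Length-`P` fitness vector.
#' @param C `(P * alpha) x D` clone matrix with fitness vector `cfit`.
#' @param cfit Length-`P * alpha` clone fitness vector.
#' @param alpha Clones per antibody.
#' @return List `W`, `fit` after selection.
#' @export
select_clones <- function(W, fit, C, cfit, alpha) {
  P <- nrow(W)
  if (nrow(C) != P * alpha || length(cfit) != P * alpha || length(fit) != P) {
    stop("select_clones(): shape mismatch", call. = FALSE)
  }
  cf <- matrix(cfit, nrow = alpha)        # column i = clones of antibody i
  maxidx <- apply(cf, 2L, which.max)      # first maximum on ties
  idxs <- (seq_len(P) - 1L) * alpha + maxidx
  best <- cfit[idxs] > fit                # strict: ties keep the parent
  W[best, ] <- C[idxs[best], , drop = FALSE]
  fit[best] <- cfit[idxs[best]]
  list(W = W, fit = fit)
}

#' Receptor editing: replace the worst antibodies
#'
#' The `n = round(P * B)` lowest-fitness antibodies (stable ascending sort,
#' half-up rounding) are replaced with fresh random draws whose fitness is
#' evaluated immediately, advancing the evaluation counter by `n`.
#'
#' @inheritParams select_clones
#' @param B Editing fraction; `round(P * B)` must be `< P`.
#' @param lb,ub Box bounds for the fresh draws.
#' @param fitness_fn Function `(batch) -> fitness vector` that advances the
#'   evaluation counter itself.
#' @return List `W`, `fit` after editing.
#' @export
receptor_edit <- function(W, fit, B, lb, ub, fitness_fn) {
  P <- nrow(W)
  n <- round_half_up(P * B)
  if (n >= P) stop("receptor_edit(): round(P * B) must be < P", call. = FALSE)
  if (n > 0) {
    worst <- order(fit)[seq_len(n)]     # stable ascending sort
    fresh <- create_antibodies(n, ncol(W), lb, ub)
    W[worst, ] <- fresh
    fit[worst] <- fitness_fn(fresh)
  }
  list(W = W, fit = fit)
}

#' Best antibody of a population
#'
#' @param W Antibody matrix; @param fit matching fitness vector.
#' @return List `gmax` (maximum fitness) and `gpar` (a copy of the row
#'   attaining it; lowest index on ties).
#' @export
find_best <- function(W, fit) {
  if (nrow(W) == 0L) stop("find_best(): empty population", call. = FALSE)
  idx <- which.max(fit)
  list(gmax = fit[idx], gpar = as.numeric(W[idx, ]))
}

# Run body with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards so fits do not perturb the session.
with_seed <- function(seed, body) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  body()
}

new_trained_model <- function(gpar, gmax, counter, trace, iterations,
                              algorithm, spec, config) {
  structure(list(theta = gpar, gmax = gmax, evaluations_used = counter$n,
                 best_trace = trace, iterations = iterations,
                 algorithm = algorithm, fitness = spec, config = config),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model: %s, fitness %s>\n", x$algorithm, x$fitness$id))
  cat(sprintf("  best fitness gmax = %.6f after %d iterations (%d evaluations)\n",
              x$gmax, x$iterations, x$evaluations_used))
  cat(sprintf("  theta (bias first, D = %d): %s\n", length(x$theta),
              paste(sprintf("%.4f", utils::head(x$theta, 6)), collapse = ", ")))
  invisible(x)
}

#' Train logistic-regression weights with the hybrid CSA-DE optimizer
#'
#' The hybrid training loop: a population of `P` antibodies (candidate
#' bias+weight vectors, `D = N + 1`) is initialized uniformly inside the
#' box bounds and scored; the evaluation counter is then reset to 0. Each
#' iteration clones every antibody `alpha` times, runs DE/rand/1/bin local
#' search over the clone pool, greedily re-selects the best clone per
#' antibody (strict improvement), receptor-edits the worst `round(P * B)`
#' antibodies, and records the population best. The loop ends at the first
#' top-of-loop check with at least `MEN` counted evaluations. Counted
#' evaluations per iteration are `P * alpha + round(P * B)`.
#'
#' @param X Feature matrix `M x N`.
#' @param y Binary labels with both classes present.
#' @param config An [optimizer_config()].
#' @param spec A [fitness_spec()]; default maximizes F1.
#' @return Object of class `trained_model` with fields `theta` (best
#'   parameter vector, bias first), `gmax` (its fitness),
#'   `evaluations_used`, `best_trace` (best fitness per iteration,
#'   non-decreasing), `iterations`.
#' @export
fit_csa_de_lr <- function(X, y, config = optimizer_config(),
                          spec = fitness_spec("f1")) {
  stopifnot(inherits(config, "optimizer_config"))
  X <- as.matrix(X)
  check_binary(y, nrow(X), "y")
  if (length(unique(y)) < 2L) {
    stop("fit_csa_de_lr(): both classes must be present", call. = FALSE)
  }
  D <- ncol(X) + 1L
  with_seed(config$seed, function() {
    counter <- new_eval_counter()
    fitness_fn <- function(batch) eval_fitness(spec, batch, X, y, counter)
    W <- create_antibodies(config$P, D, config$lb, config$ub)
    fit <- fitness_fn(W)
    counter$n <- 0L                     # budget excludes the initial scoring
    trace <- numeric(0)
    iterations <- 0L
    best <- find_best(W, fit)
    while (counter$n < config$MEN) {
      C <- clone_antibodies(W, config$alpha)
      C <- de_local_search(C, config$P, config$alpha, config$sf, config$cr,
                           config$lb, config$ub)
      cfit <- fitness_fn(C)
      sel <- select_clones(W, fit, C, cfit, config$alpha)
      W <- sel$W; fit <- sel$fit
      ed <- receptor_edit(W, fit, config$B, config$lb, config$ub, fitness_fn)
      W <- ed$W; fit <- ed$fit
      best <- find_best(W, fit)
      iterations <- iterations + 1L
      trace <- c(trace, best$gmax)
    }
    new_trained_model(best$gpar, best$gmax, counter, trace, iterations,
                      "csa_de_lr", spec, config)
  })
}
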