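#' Inverse (segment-reversal) hyper-mutation
#'
#' Picks random positions `j`, `l` with `|j - l| > 2` and reverses the
#' contiguous segment between them (inclusive), preserving the coordinate
#' multiset. For vectors too short to satisfy the constraint (`D < 4`) the
#' operator falls back to [pairwise_mutation()].
#'
#' @param v Numeric parameter vector.
#' @return Mutated vector of the same length.
#' @export
inverse_mutation <- function(v) {
  D <- length(v)
  if (D < 4L) return(pairwise_mutation(v))
  repeat {
    jl <- sample.int(D, 2L)
    if (abs(jl[1L] - jl[2L]) > 2L) break
  }
  a <- min(jl); b <- max(jl)
  v[a:b] <- v[b:a]
  v
}

#' Pair-wise (swap) hyper-mutation
#'
#' Exchanges two distinct random coordinates, preserving the multiset.
#'
#' @param v Numeric parameter vector of length >= 2.
#' @return Mutated vector of the same length.
#' @export
pairwise_mutation <- function(v) {
  if (length(v) < 2L) stop("pairwise_mutation(): need length >= 2", call. = FALSE)
  jl <- sample.int(length(v), 2L)
  v[jl] <- v[rev(jl)]
  v
}

#' Train logistic-regression weights with classic clonal selection
#'
#' CLONALG ablation: each iteration clones every antibody `alpha` times and
#' scores the clones; each clone then attempts an inverse (segment
#' reversal) hyper-mutation, accepted iff strictly fitter, otherwise a
#' pair-wise swap mutation, accepted iff strictly fitter (one counted
#' evaluation per attempted mutant). Each antibody is replaced by its best
#' clone, then the worst `round(P * B)` antibodies are receptor-edited.
#' Budget semantics match [fit_csa_de_lr()]: the initial population scoring
#' is not counted, and the loop stops at the first top-of-loop check with
#' the counter at `MEN`. `sf` and `cr` are ignored.
#'
#' @inheritParams fit_csa_de_lr
#' @return A `trained_model`.
#' @export
fit_csa_lr <- function(X, y, config = optimizer_config(),
                       spec = fitness_spec("f1")) {
  stopifnot(inherits(config, "optimizer_config"))
  X <- as.matrix(X)
  check_binary(y, nrow(X), "y")
  if (length(unique(y)) < 2L) {
    stop("fit_csa_lr(): both classes must be present", call. = FALSE)
  }
  D <- ncol(X) + 1L
  with_seed(config$seed, function() {
    counter <- new_eval_counter()
    fitness_fn <- function(batch) eval_fitness(spec, batch, X, y, counter)
    W <- create_antibodies(config$P, D, config$lb, config$ub)
    fit <- fitness_fn(W)
    counter$n <- 0L
    trace <- numeric(0)
    iterations <- 0L
    best <- find_best(W, fit)
    while (counter$n < config$MEN) {
      C <- clone_antibodies(W, config$alpha)
      cfit <- fitness_fn(C)
      for (i in seq_len(nrow(C))) {
        sig <- inverse_mutation(C[i, ])
        sfit <- fitness_fn(matrix(sig, nrow = 1L))
        if (sfit > cfit[i]) {
          C[i, ] <- sig; cfit[i] <- sfit
        } else {
          sig <- pairwise_mutation(C[i, ])
          sfit <- fitness_fn(matrix(sig, nrow = 1L))
          if (sfit > cfit[i]) {
            C[i, ] <- sig; cfit[i] <- sfit
          }
        }
      }
      # re-selection: each antibody takes its topmost-affinity clone
      # (unconditional as printed; clones start as parent copies and
      # mutants are only accepted when strictly better, so never worse)
      cf <- matrix(cfit, nrow = config$alpha)
      maxidx <- apply(cf, 2L, which.max)
      idxs <- (seq_len(config$P) - 1L) * config$alpha + maxidx
      W <- C[idxs, , drop = FALSE]
      fit <- cfit[idxs]
      ed <- receptor_edit(W, fit, config$B, config$lb, config$ub, fitness_fn)
      W <- ed$W; fit <- ed$fit
      best <- find_best(W, fit)
      iterations <- iterations + 1L
      trace <- c(trace, best$gmax)
    }
    new_trained_model(best$gpar, best$gmax, counter, trace, iterations,
                      "csa_lr", spec, config)
  })
}

#' Train logistic-regression weights with plain differential evolution
#'
#' Generational DE/rand/1/bin ablation: for each member, a mutant is built
#' from three distinct other members (`base + sf * (d2 - d1)`), crossed
#' binomially (`u <= cr`, no forced coordinate), clipped to the bounds, and
#' accepted iff strictly fitter than its parent. The population fitness is
#' therefore pointwise non-decreasing. Counts `P` evaluations per
#' generation; the initial scoring is not counted. `alpha` and `B` are
#' ignored.
#'
#' @inheritParams fit_csa_de_lr
#' @return A `trained_model`.
#' @export
fit_de_lr <- function(X, y, config = optimizer_config(),
                      spec = fitness_spec("f1")) {
  stopifnot(inherits(config, "optimizer_config"))
  X <- as.matrix(X)
  check_binary(y, nrow(X), "y")
  if (length(unique(y)) < 2L) {
    stop("fit_de_lr(): both classes must be present", call. = FALSE)
  }
  if (config$P < 4) stop("fit_de_lr(): P >= 4 required", call. = FALSE)
  D <- ncol(X) + 1L
  with_seed(config$seed, function() {
    counter <- new_eval_counter()
    fitness_fn <- function(batch) eval_fitness(spec, batch, X, y, counter)
    W <- create_antibodies(config$P, D, config$lb, config$ub)
    fit <- fitness_fn(W)
    counter$n <- 0L
    trace <- numeric(0)
    iterations <- 0L
    best <- find_best(W, fit)
    while (counter$n < config$MEN) {
      trials <- W
      for (i in seq_len(config$P)) {
        inds <- seq_len(config$P)[-i]
        donors <- inds[sample.int(length(inds), 3L)]
        arr <- W[donors[1L], ] + config$sf * (W[donors[3L], ] - W[donors[2L], ])
        u <- stats::runif(D)
        rho <- u <= config$cr
        trial <- W[i, ]
        if (any(rho)) {
          vec <- arr[rho]
          vec[vec < config$lb] <- config$lb
          vec[vec > config$ub] <- config$ub
          trial[rho] <- vec
        }
        trials[i, ] <- trial
      }
      tfit <- fitness_fn(trials)
      better <- tfit > fit
      W[better, ] <- trials[better, , drop = FALSE]
      fit[better] <- tfit[better]
      best <- find_best(W, fit)
      iterations <- iterations + 1L
      trace <- c(trace, best$gmax)
    }
    new_trained_model(best$gpar, best$gmax, counter, trace, iterations,
                      "de_lr", spec, config)
  })
}

#' Train with a named algorithm
#'
#' Dispatcher over the three trainers, keyed the same way as the
#' configuration-file interface.
#'
#' @inheritParams fit_csa_de_lr
#' @param algorithm `"csa_de_lr"`, `"csa_lr"`, or `"de_lr"`.
#' @return A `trained_model`.
#' @export
fit_model <- function(X, y, config = optimizer_config(),
                      spec = fitness_spec("f1"),
                      algorithm = c("csa_de_lr", "csa_lr", "de_lr")) {
  algorithm <- match.arg(algorithm)
  fn <- switch(algorithm, csa_de_lr = fit_csa_de_lr,
               csa_lr = fit_csa_lr, de_lr = fit_de_lr)
  fn(X, y, config, spec)
}
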