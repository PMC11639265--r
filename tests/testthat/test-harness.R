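# small shared ingredients: quick budgets keep the suite fast
hds <- make_logistic_data(120, 2, c(-3, 4, 2), noise = "bernoulli", seed = 14)
hcfg <- optimizer_config(P = 6, alpha = 2, B = 0.2, MEN = 120, seed = 1)

test_that("cross_validate produces a consistent per-fold report", {
  cv <- cross_validate(hds, "csa_de_lr", hcfg, fitness_spec("f1"),
                       k = 5, seed = 2)
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$folds), 5L)
  expect_length(cv$models, 5L)
  # mean/sd recomputable from the fold list (population formula)
  expect_equal(unname(cv$mean), unname(colMeans(cv$folds)), tolerance = 1e-12)
  expect_equal(unname(cv$sd),
               unname(apply(cv$folds, 2, function(v) sqrt(mean((v - mean(v))^2)))),
               tolerance = 1e-12)
  expect_true(all(cv$folds$acc >= 0 & cv$folds$acc <= 1))
  expect_true(all(cv$folds$mcc >= -1 & cv$folds$mcc <= 1))
  # reproducible end to end
  cv2 <- cross_validate(hds, "csa_de_lr", hcfg, fitness_spec("f1"),
                        k = 5, seed = 2)
  expect_identical(cv$folds, cv2$folds)
})

test_that("a constant all-zero classifier scores the fold positive rate", {
  # probabilities are exactly 0.5 -> every prediction is class 1, so
  # per-fold accuracy must equal the fold's positive rate
  folds <- kfold_split(hds, k = 5, seed = 9)
  for (f in seq_along(folds)) {
    yte <- hds$y[folds[[f]]]
    p <- predict_proba(rep(0, 3), hds$X[folds[[f]], ])
    rep <- suppressWarnings(metric_report(yte, p))
    expect_equal(rep$acc, mean(yte == 1))
  }
})

test_that("formatting follows the percent/rate table conventions", {
  cv <- cross_validate(hds, "de_lr", hcfg, fitness_spec("error"),
                       k = 4, seed = 3)
  fmt <- format_cv_report(cv)
  expect_named(fmt, c("acc", "f1", "mcc", "roc_auc", "fnr", "fpr"))
  expect_match(fmt[["acc"]], "^\\d+\\.\\d{2} ± \\d+\\.\\d{3}$")
  expect_match(fmt[["fnr"]], "^\\d+\\.\\d{3} ± \\d+\\.\\d{3}$")
  # the printed accuracy is the mean x100 at 2 decimals
  expect_equal(as.numeric(sub(" ±.*", "", fmt[["acc"]])),
               round(100 * cv$mean[["acc"]], 2))
})

test_that("mean_feature_weights averages folds, bias kept separate", {
  w <- mean_feature_weights(list(c(9, 1, 2), c(11, 3, 4)), c("a", "b"))
  expect_equal(unname(w$mean), c(2, 3))
  expect_equal(w$bias_mean, 10)
  expect_equal(dim(w$table), c(2L, 2L))
  # permutation invariance and single-fold identity
  wp <- mean_feature_weights(list(c(11, 3, 4), c(9, 1, 2)), c("a", "b"))
  expect_equal(wp$mean, w$mean)
  w1 <- mean_feature_weights(list(c(5, 7, 8)), c("a", "b"))
  expect_equal(unname(w1$mean), c(7, 8))
  expect_error(mean_feature_weights(list(c(1, 2), c(1, 2, 3))),
               "inconsistent")
  # works off trained models too
  cv <- cross_validate(hds, "csa_de_lr", hcfg, k = 3, seed = 4)
  wm <- mean_feature_weights(cv$models, hds$feature_names)
  expect_named(wm$mean, c("x1", "x2"))
  expect_equal(unname(wm$mean), unname(colMeans(wm$table)))
})

test_that("random_search_tune samples inside the space and reproduces", {
  sp <- default_search_space("csa_de_lr")
  tn <- random_search_tune(hds, "csa_de_lr", sp, iterations = 4, seed = 5,
                           k = 3, MEN = 60)
  expect_s3_class(tn$best_config, "optimizer_config")
  expect_equal(nrow(tn$trials), 4L)
  for (nm in names(sp)) {
    expect_true(all(tn$trials[[nm]] >= sp[[nm]]$low))
    expect_true(all(tn$trials[[nm]] <= sp[[nm]]$high))
    if (sp[[nm]]$integer) {
      expect_true(all(tn$trials[[nm]] == round(tn$trials[[nm]])))
    }
  }
  expect_equal(tn$best_score, max(tn$trials$score))
  tn2 <- random_search_tune(hds, "csa_de_lr", sp, iterations = 4, seed = 5,
                            k = 3, MEN = 60)
  expect_identical(tn$trials, tn2$trials)
  # iterations = 1 returns that single sample
  tn1 <- random_search_tune(hds, "de_lr", default_search_space("de_lr"),
                            iterations = 1, seed = 6, k = 3, MEN = 40)
  expect_equal(nrow(tn1$trials), 1L)
  expect_equal(tn1$best_score, tn1$trials$score[1])
  expect_error(random_search_tune(hds, space = list(), iterations = 2),
               "empty")
})

test_that("wilcoxon_compare: symmetry, exact branch, approx branch", {
  a <- c(5, 6, 7, 8, 9, 10)
  b <- c(1, 2, 3, 4, 4.5, 5.5)
  w <- wilcoxon_compare(a, b)
  expect_true(w$exact)
  expect_equal(w$p_value, 0.03125)              # 2 / 2^6
  expect_equal(wilcoxon_compare(b, a)$p_value, w$p_value)
  expect_error(wilcoxon_compare(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)),
               "zero")
  expect_error(wilcoxon_compare(1:3, 1:3), "length >= 5")
  # large n uses the normal approximation and stays in (0, 1]
  set.seed(23)
  x <- stats::rnorm(40); y <- x + stats::rnorm(40, 0.2)
  wl <- wilcoxon_compare(x, y)
  expect_false(wl$exact)
  expect_gt(wl$p_value, 0)
  expect_lte(wl$p_value, 1)
  # approximation is sane vs the exact branch near the cutoff
  x2 <- stats::rnorm(25); y2 <- x2 + stats::rnorm(25, 0.3)
  we <- wilcoxon_compare(x2, y2)
  expect_true(we$exact)
})

test_that("exact branch agrees with full sign enumeration (n <= 10)", {
  set.seed(29)
  for (rep in 1:25) {
    n <- sample(5:10, 1)
    a <- stats::rnorm(n)
    b <- a + sample(c(-1, 1), n, replace = TRUE) *
      sample(seq(0.5, 3, by = 0.5), n, replace = TRUE)  # ties likely
    got <- wilcoxon_compare(a, b)
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_wilcoxon(a, b), tolerance = 1e-12)
  }
})

test_that("mirrored-pair enlargement matches enumeration; top-rank pair weakens", {
  a <- c(5, 6, 7, 8, 9, 10)
  b <- c(1, 2, 3, 4, 4.5, 5.5)
  p0 <- wilcoxon_compare(a, b)$p_value
  expect_equal(p0, 2 / 64)
  # a mirrored pair outranking every original difference dilutes the
  # one-sided signal: p rises (value frozen from exact enumeration)
  p_top <- wilcoxon_compare(c(a, 7, -7), c(b, 0, 0))$p_value
  expect_equal(p_top, 38 / 256, tolerance = 1e-12)
  expect_gte(p_top, p0)
  expect_equal(p_top, oracle_wilcoxon(c(a, 7, -7), c(b, 0, 0)),
               tolerance = 1e-12)
  # a low-rank mirrored pair instead sharpens the tail (6/256 < 2/64):
  # the implementation must still match enumeration exactly
  p_low <- wilcoxon_compare(c(a, 0.7, -0.7), c(b, 0, 0))$p_value
  expect_equal(p_low, 6 / 256, tolerance = 1e-12)
  expect_equal(p_low, oracle_wilcoxon(c(a, 0.7, -0.7), c(b, 0, 0)),
               tolerance = 1e-12)
})

test_that("run_experiment writes recomputable tables and JSON", {
  out <- withr::local_tempdir()
  plan <- list(
    datasets = list(synth = hds),
    algorithms = c("csa_de_lr", "de_lr"),
    seeds = 1:5, k = 3, fitness = "f1",
    config = optimizer_config(P = 5, alpha = 2, B = 0.2, MEN = 40, seed = 1)
  )
  rep1 <- run_experiment(plan, out)
  expect_true(file.exists(file.path(out, "metrics_synth.csv")))
  expect_true(file.exists(file.path(out, "weights_synth_csa_de_lr.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  # 2 algorithms x 5 seeds -> a paired 5-row sample per metric + wilcoxon
  expect_equal(nrow(rep1$synth$csa_de_lr$per_seed_mean), 5L)
  expect_true(is.numeric(rep1$synth$wilcoxon_vs_first$de_lr$acc))
  # JSON round-trips and re-running is identical
  js <- jsonlite::read_json(file.path(out, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$synth$csa_de_lr$per_seed_mean$acc,
               rep1$synth$csa_de_lr$per_seed_mean$acc, tolerance = 1e-12)
  out2 <- withr::local_tempdir()
  rep2 <- run_experiment(plan, out2)
  expect_equal(rep1$synth$csa_de_lr$per_seed_mean,
               rep2$synth$csa_de_lr$per_seed_mean)
  # every number in the formatted table is recomputable from the folds
  folds1 <- rep1$synth$csa_de_lr$folds[[1]]
  tab <- utils::read.csv(file.path(out, "metrics_synth.csv"),
                         check.names = FALSE)
  acc_cell <- tab[tab$method == "csa_de_lr", "acc"]
  expect_equal(as.numeric(sub(" ±.*", "", acc_cell)),
               round(100 * mean(folds1$acc), 2))
})

test_that("the CLI generates, evaluates and trains end to end", {
  tmp <- withr::local_tempfile(fileext = ".dat")
  ds <- run_cli(c("synth", "--n", "60", "--d", "13", "--seed", "3",
                  "--out", tmp))
  expect_true(file.exists(tmp))
  expect_s3_class(ds, "lr_dataset")
  back <- load_dataset(tmp, "statlog")
  expect_equal(nrow(back$X), 60L)
  modelj <- withr::local_tempfile(fileext = ".json")
  m <- run_cli(c("train", "--dataset", tmp, "--dialect", "statlog",
                 "--algorithm", "de_lr", "--fitness", "error",
                 "--men", "100", "--seed", "2", "--out", modelj))
  expect_s3_class(m, "trained_model")
  parsed <- jsonlite::read_json(modelj)
  expect_equal(parsed$algorithm, "de_lr")
  expect_length(parsed$weights, 13L)
  expect_error(run_cli(character(0)), "usage")
  expect_error(run_cli(c("train")), "--dataset")
  expect_error(run_cli(c("bogus")), "unknown subcommand")
})
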