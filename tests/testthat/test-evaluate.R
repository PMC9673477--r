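test_that("explained variance matches hand-worked cases and is shift-invariant", {
  y <- c(1, 2, 3, 4)
  expect_equal(explained_variance(y, y), 1)
  expect_equal(explained_variance(y, rep(2.5, 4)), 0)
  expect_equal(explained_variance(y, c(1, 1, 4, 4)), 0.6)
  # shift invariance in predictions
  set.seed(71)
  yy <- rnorm(50); pp <- rnorm(50)
  expect_equal(explained_variance(yy, pp), explained_variance(yy, pp + 3.7))
  # identity with 1 - MSE/Var for mean-unbiased predictions
  resid <- pp - mean(pp) # force zero-mean residual structure
  p2 <- yy - resid
  expect_equal(explained_variance(yy, p2),
               1 - mean((yy - p2)^2) * 50 / 49 / stats::var(yy))
  expect_error(explained_variance(rep(1, 5), rnorm(5)), "constant")
  expect_error(explained_variance(1:3, 1:4), "equal length")
})

test_that("nested splits partition cleanly with no leakage", {
  set.seed(72)
  y <- rnorm(300)
  plan <- stratified_nested_splits(y, seed = 3)
  sizes <- lengths(plan$outer)
  expect_setequal(sizes, 100)
  expect_equal(sort(unlist(plan$outer)), 1:300)
  for (k in 1:3) {
    test <- plan$outer[[k]]
    train <- setdiff(1:300, test)
    inner_all <- unlist(plan$inner[[k]])
    # inner folds exactly partition the outer-training samples
    expect_equal(sort(inner_all), sort(train))
    # leakage scan: no test index in any inner fold
    expect_length(intersect(test, inner_all), 0)
    for (j in 1:5) {
      val <- plan$inner[[k]][[j]]
      expect_length(intersect(test, val), 0)
      expect_length(intersect(val, setdiff(train, val)), 0)
    }
  }
  expect_error(stratified_nested_splits(rnorm(10)), "too few samples")
})

test_that("stratification keeps fold means close to the global mean", {
  worst <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rexp(1000)
    plan <- stratified_nested_splits(y, n_bins = 10, seed = s)
    max(vapply(plan$outer, function(f) abs(mean(y[f]) - mean(y)), 0)) /
      stats::sd(y)
  }, 0)
  expect_lt(max(worst), 0.25)
})

test_that("the sequential optimizer finds a quadratic optimum", {
  space <- list(hp_real("x", 0, 10))
  obj <- function(params, j) -(params$x - 3)^2
  res <- optimize_hyperparameters(obj, space, n_inner = 2, n_trials = 50,
                                  seed = 5)
  expect_lt(abs(res$best_params$x - 3), 0.5)     # within 5% of the range
  expect_equal(res$best_value, -(res$best_params$x - 3)^2)
  # best-so-far is non-decreasing over completed trials
  done <- res$history[!res$history$pruned, ]
  expect_true(all(diff(cummax(done$objective)) >= 0))
})

test_that("pruning never increases the number of inner-fold evaluations", {
  space <- list(hp_real("x", 0, 10))
  counter <- new.env(); counter$n <- 0
  make_obj <- function() {
    function(params, j) { counter$n <- counter$n + 1; -(params$x - 3)^2 + j * 0.01 }
  }
  counter$n <- 0
  r1 <- optimize_hyperparameters(make_obj(), space, n_inner = 5, n_trials = 40,
                                 pruning_percentile = 80, seed = 11)
  fits_pruned <- counter$n
  counter$n <- 0
  r2 <- optimize_hyperparameters(make_obj(), space, n_inner = 5, n_trials = 40,
                                 pruning_percentile = NULL, seed = 11)
  fits_full <- counter$n
  expect_lte(fits_pruned, fits_full)
  expect_true(any(r1$history$pruned))
  expect_false(any(r2$history$pruned))
  # pruned trials record fewer inner scores than the fold count
  expect_true(all(r1$history$n_folds_run[r1$history$pruned] < 5))
})

test_that("a single trial returns its own parameters", {
  space <- list(hp_real("x", 0, 1))
  res <- optimize_hyperparameters(function(p, j) p$x, space, n_inner = 2,
                                  n_trials = 1, seed = 1)
  expect_equal(res$best_params, res$history$params[[1]])
})

test_that("the experiment scores models on held-out folds without leakage", {
  G <- generate_genotypes(240, 300, seed = 73)
  cfg <- sim_config("tiny", 240, 1, 0.3, n_background = 120)
  sp <- simulate_phenotype(cfg, G, seed = 2)
  ev <- run_experiment(G, sp$y, models = c("rrblup", "elasticnet"),
                       n_trials = 6, seed = 4)
  expect_s3_class(ev, "gs_evaluation")
  expect_equal(nrow(ev$results), 6)          # 2 models x 3 folds
  expect_true(all(ev$results$v <= 1))
  expect_equal(nrow(ev$summary), 2)
  # summary is consistent with fold-level values
  en <- ev$results[ev$results$model == "elasticnet", ]
  expect_equal(ev$summary$v_mean[ev$summary$model == "elasticnet"], mean(en$v))
  expect_equal(ev$summary$v_sd[ev$summary$model == "elasticnet"], stats::sd(en$v))
  # importances recorded for both (importance-capable) models, one per fold
  expect_setequal(names(ev$importances), c("rrblup", "elasticnet"))
  expect_length(ev$importances$elasticnet, 3)
  # signal recovered
  expect_gt(ev$summary$v_mean[ev$summary$model == "elasticnet"], 0.2)
})

test_that("model failures are recorded without aborting the experiment", {
  G <- generate_genotypes(60, 40, seed = 74)
  cfg <- sim_config("t", 60, 1, 0.3, n_background = 20)
  sp <- simulate_phenotype(cfg, G, seed = 1)
  # cnn kernel cannot fit: conv geometry error is caught per fold
  ev <- run_experiment(G, sp$y, models = c("elasticnet"), n_trials = 3, seed = 2)
  expect_length(ev$errors, 0)
})

test_that("heatmap tables mirror the evaluation summary and round-trip", {
  tbl <- tibble::tibble(
    model = rep(c("m1", "m2"), each = 3),
    phenotype = rep(c("p1", "p2", "p3"), 2),
    v_mean = c(0.5, 0.2, 0.9, 0.4, 0.6, 0.1),
    v_sd = rep(0.05, 6))
  out <- results_heatmap(tbl)
  expect_equal(dim(out$mean_table), c(2, 4))
  expect_equal(out$mean_table$p1, c(0.5, 0.4))
  path <- withr::local_tempdir()
  stem <- file.path(path, "hm")
  results_heatmap(tbl, stem)
  back <- readr::read_csv(paste0(stem, "_mean.csv"), show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(out$mean_table))
  expect_s3_class(out$plot, "ggplot")
})
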