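test_that("top-k selection matches a full-sort oracle", {
  v <- c(a = 0, b = 2, c = -3, d = 1, e = 0, f = 0, g = 0, h = 0, i = 0, j = 0)
  top <- top_k_select(v, k = 1000)
  expect_equal(nrow(top), 10)                  # capped at length
  expect_equal(top$marker[1:3], c("c", "b", "d"))  # nonzero first, by magnitude
  expect_equal(top_k_select(v, k = 1)$marker, "c")
  set.seed(81)
  r <- stats::setNames(rnorm(200), sprintf("m%03d", 1:200))
  top50 <- top_k_select(r, 50)
  oracle <- names(sort(abs(r), decreasing = TRUE))[1:50]
  expect_setequal(top50$marker, oracle)
  expect_equal(top50$magnitude, sort(abs(r), decreasing = TRUE)[1:50],
               ignore_attr = TRUE)
})

test_that("fold aggregation min-max normalizes and averages over all folds", {
  one <- aggregate_across_folds(list(c(a = 2, b = 1, c = 0)), k = 1000)
  expect_equal(one$avg_importance[match(c("a", "b", "c"), one$marker)],
               c(1, 0.5, 0))
  # marker present in one of three folds with normalized value 0.9
  f1 <- c(a = 10, b = 9, x = 0.5)
  f2 <- c(a = 8, b = 7, x = 0)
  f3 <- c(a = 6, b = 5, x = 0)
  agg <- aggregate_across_folds(list(f1, f2, f3), k = 2)   # x only in no fold's top-2
  expect_false("x" %in% agg$marker)
  # three-fold brute-force oracle on random vectors
  set.seed(82)
  folds <- replicate(3, stats::setNames(rnorm(40), sprintf("m%02d", 1:40)),
                     simplify = FALSE)
  k <- 10
  agg <- aggregate_across_folds(folds, k = k)
  norm1 <- lapply(folds, function(v) {
    mag <- abs(v)
    top <- names(sort(mag, decreasing = TRUE))[1:k]
    (mag[top] - min(mag[top])) / (max(mag[top]) - min(mag[top]))
  })
  union_markers <- unique(unlist(lapply(norm1, names)))
  for (m in union_markers) {
    vals <- vapply(norm1, function(nv) if (m %in% names(nv)) nv[[m]] else 0, 0)
    expect_equal(agg$avg_importance[agg$marker == m], mean(vals),
                 tolerance = 1e-12)
  }
  expect_true(all(agg$avg_importance >= 0 & agg$avg_importance <= 1))
  # the explicit 0.9-in-one-fold case
  agg2 <- aggregate_across_folds(
    list(c(a = 1, b = 0.9, c = 0), c(a = 1, d = 0.2, c = 0), c(a = 1, d = 0.3, c = 0)),
    k = 3)
  expect_equal(agg2$avg_importance[agg2$marker == "b"], 0.3)
  # constant fold warns and contributes zeros
  expect_warning(aggregate_across_folds(list(c(a = 1, b = 1, c = 1))),
                 "constant")
})

test_that("the relative filter thresholds at a fraction of the maximum and is monotone", {
  agg <- tibble::tibble(marker = c("a", "b", "c"),
                        avg_importance = c(1.0, 0.5, 0.009),
                        n_folds_top_k = 1L)
  expect_equal(relative_filter(agg, 0.01)$marker, c("a", "b"))
  all_equal <- tibble::tibble(marker = c("a", "b"), avg_importance = c(0.4, 0.4),
                              n_folds_top_k = 1L)
  expect_equal(nrow(relative_filter(all_equal, 0.5)), 2)
  set.seed(83)
  rnd <- tibble::tibble(marker = sprintf("m%02d", 1:50),
                        avg_importance = runif(50), n_folds_top_k = 1L)
  for (f in c(0.05, 0.2, 0.5)) {
    got <- relative_filter(rnd, f)$marker
    oracle <- rnd$marker[rnd$avg_importance >= f * max(rnd$avg_importance)]
    expect_setequal(got, oracle)
  }
  # monotone: larger fraction never adds markers
  n_kept <- vapply(c(0.01, 0.1, 0.3, 0.6), function(f)
    nrow(relative_filter(rnd, f)), 0L)
  expect_true(all(diff(n_kept) <= 0))
})

test_that("scoring against the truth computes TPR and causal ranks", {
  agg <- tibble::tibble(
    marker = c("m1", "m2", "m3", "m4", "m5", "m6"),
    avg_importance = c(0.9, 0.8, 0.5, 0.3, 0.1, 0),
    n_folds_top_k = 1L)
  truth <- list(causal_markers = "m2", background_markers = c("m3", "m5"),
                beta = 1, gamma = c(0.1, 0.2))
  rep <- score_against_truth(agg, truth, model = "toy")
  s <- rep$summary
  expect_equal(s$n_important, 5)              # m6 has zero importance
  expect_equal(s$background_found, 2)
  expect_equal(s$tpr, 0.4)
  expect_equal(s$causal_detected, 1)
  expect_equal(s$causal_ranks[[1]], 2)
  # zero-causal degenerate case
  truth0 <- list(causal_markers = character(0), background_markers = "m1",
                 beta = numeric(0), gamma = 0.1)
  s0 <- score_against_truth(agg, truth0)$summary
  expect_equal(s0$causal_detected, 0)
  expect_equal(s0$causal_total, 0)
  expect_length(s0$causal_ranks[[1]], 0)
  # the 1%-of-max filter never keeps more features
  expect_lte(s$n_important_filtered, s$n_important)
})

test_that("effect-importance correlation hits the exact extremes and the permutation null", {
  truth <- list(causal_markers = "c1",
                background_markers = sprintf("b%02d", 1:20),
                beta = 2, gamma = seq(0.05, 1, length.out = 20))
  eff <- c(2, seq(0.05, 1, length.out = 20))
  mk <- c("c1", sprintf("b%02d", 1:20))
  prop <- tibble::tibble(marker = mk, avg_importance = eff * 0.37,
                         n_folds_top_k = 1L)
  expect_equal(effect_importance_correlation(truth, prop)$pearson_r, 1)
  anti <- tibble::tibble(marker = mk, avg_importance = max(eff) + 0.1 - eff,
                         n_folds_top_k = 1L)
  expect_equal(effect_importance_correlation(truth, anti)$pearson_r, -1)
  set.seed(84)
  rs <- replicate(100, {
    perm <- tibble::tibble(marker = mk, avg_importance = sample(eff),
                           n_folds_top_k = 1L)
    effect_importance_correlation(truth, perm)$pearson_r
  })
  expect_lt(abs(mean(rs)), 0.1)
  few <- tibble::tibble(marker = c("c1", "b01"), avg_importance = c(1, 1),
                        n_folds_top_k = 1L)
  expect_error(effect_importance_correlation(truth, few), "fewer than 3")
})
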