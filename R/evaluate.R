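#' Stratified nested cross-validation split plan
#'
#' Samples are grouped into quantile bins of the phenotype; outer test
#' folds and, within each outer training set, inner validation folds are
#' then drawn stratified by bin, so the phenotypic distribution stays
#' approximately the same across all splits. Bins smaller than the fold
#' count are merged with their neighbour before splitting.
#'
#' @param y numeric phenotype vector.
#' @param n_outer number of outer (test) folds.
#' @param n_inner number of inner (validation) folds per outer fold.
#' @param n_bins number of quantile bins for stratification.
#' @param seed integer seed.
#' @return A `gs_split_plan`: `outer` (list of test index vectors,
#'   pairwise disjoint, union = all samples), `inner` (per outer fold, a
#'   list of validation index vectors partitioning the outer-training
#'   samples), `bin_labels`, `seed`.
#' @export
stratified_nested_splits <- function(y, n_outer = 3, n_inner = 5,
                                     n_bins = 10, seed = 1L) {
  n <- length(y)
  stopifnot(n_bins >= 2, n_outer >= 2, n_inner >= 2)
  if (n < n_outer * n_inner)
    stop("too few samples for the requested fold structure", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  qs <- stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bins <- as.integer(cut(y, breaks = unique(qs), include.lowest = TRUE))
  # merge bins with fewer members than the larger fold count upward
  min_size <- max(n_outer, n_inner)
  repeat {
    sizes <- table(bins)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) == 1) break
    b <- as.integer(small[1])
    lv <- sort(unique(bins))
    nb <- if (b == max(lv)) lv[which(lv == b) - 1] else lv[which(lv == b) + 1]
    bins[bins == b] <- nb
  }

  strat_partition <- function(idx, k) {
    folds <- vector("list", k)
    for (b in unique(bins[idx])) {
      members <- idx[bins[idx] == b]
      members <- members[sample.int(length(members))]
      assign_to <- (seq_along(members) + sample.int(k, 1)) %% k + 1
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], members[assign_to == f])
    }
    lapply(folds, sort)
  }

  outer <- strat_partition(seq_len(n), n_outer)
  inner <- lapply(outer, function(test) {
    train <- setdiff(seq_len(n), test)
    strat_partition(train, n_inner)
  })
  structure(list(outer = outer, inner = inner, bin_labels = bins,
                 n_outer = n_outer, n_inner = n_inner,
                 seed = as.integer(seed)),
            class = "gs_split_plan")
}

#' @export
print.gs_split_plan <- function(x, ...) {
  cat(sprintf("<gs_split_plan> %d outer x %d inner folds over %d samples (%d bins)\n",
              x$n_outer, x$n_inner, length(x$bin_labels),
              length(unique(x$bin_labels))))
  invisible(x)
}

#' Explained variance
#'
#' `v = 1 - Var(y - y_hat) / Var(y)`; at most 1, unbounded below, equal to
#' 0 for any constant prediction and invariant to adding a constant to the
#' predictions. Sample variances use the n-1 convention (the ratio is
#' invariant to that choice when applied consistently).
#'
#' @param y true values.
#' @param y_hat predictions.
#' @export
explained_variance <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat) || length(y) < 2)
    stop("y and y_hat must have equal length >= 2", call. = FALSE)
  vy <- stats::var(y)
  if (vy == 0) stop("explained variance undefined for constant y", call. = FALSE)
  1 - stats::var(y - y_hat) / vy
}

# ---- sequential hyperparameter search --------------------------------------

hp_value_from_u <- function(p, u) {
  switch(p$type,
    real = p$low + u * (p$high - p$low),
    logreal = exp(log(p$low) + u * (log(p$high) - log(p$low))),
    int = as.integer(p$low + floor(u * (p$high - p$low + 1))),
    categorical = p$choices[[ceiling(u * length(p$choices))]])
}

hp_sample_uniform <- function(space) {
  out <- list()
  for (p in space) out[[p$name]] <- hp_value_from_u(p, stats::runif(1))
  out
}

# stratified (Latin-hypercube-style) startup draws: each parameter's range
# is covered by construction, so no region is missed before guided
# sampling starts
hp_startup_plan <- function(space, n) {
  lapply(stats::setNames(space, vapply(space, `[[`, "", "name")),
         function(p) {
           u <- (sample.int(n) - stats::runif(n)) / n
           lapply(u, function(ui) hp_value_from_u(p, max(ui, 1e-12)))
         })
}

# density-guided proposal: perturb values from the better-scoring trials
hp_sample_guided <- function(space, good_params) {
  base <- good_params[[sample.int(length(good_params), 1)]]
  out <- list()
  for (p in space) {
    v <- base[[p$name]]
    out[[p$name]] <- switch(p$type,
      real = {
        s <- (p$high - p$low) / 8
        min(max(stats::rnorm(1, v, s), p$low), p$high)
      },
      logreal = {
        s <- (log(p$high) - log(p$low)) / 8
        exp(min(max(stats::rnorm(1, log(v), s), log(p$low)), log(p$high)))
      },
      int = {
        s <- max((p$high - p$low) / 8, 0.5)
        as.integer(min(max(round(stats::rnorm(1, v, s)), p$low), p$high))
      },
      categorical = {
        # mostly keep the good choice, sometimes explore
        if (stats::runif(1) < 0.7) v
        else p$choices[[sample.int(length(p$choices), 1)]]
      })
  }
  out
}

#' Sequential hyperparameter optimization with percentile pruning
#'
#' Maximizes the mean inner-fold explained variance over `n_trials`
#' sequential trials. The first `n_startup` trials cover the space with
#' stratified (Latin-hypercube-style) draws so that no parameter region is
#' missed; later trials are guided toward the region of the
#' best-scoring quartile of completed trials (density-based proposals with
#' occasional uniform exploration), so knowledge of already tested
#' settings steers the search. After each inner fold, a trial is pruned if
#' its running mean score is below the `pruning_percentile`-th percentile
#' of the completed trials' running means at the same step; the rule is
#' inactive until `warmup` trials have completed.
#'
#' @param objective_fun `function(params, fold_idx)` returning the score of
#'   one inner fold (higher is better).
#' @param space hyperparameter space (list of [hp_real()]-style
#'   descriptors); an empty space runs a single trial.
#' @param n_inner number of inner folds per trial.
#' @param n_trials trial budget.
#' @param pruning_percentile percentile (0-100) below which a trial is
#'   pruned; `NULL` disables pruning.
#' @param warmup completed-trial count before pruning activates.
#' @param n_startup stratified space-covering trials before guided
#'   proposals start.
#' @param seed integer seed.
#' @return list with `best_params`, `best_value`, and `history` (a tibble:
#'   trial id, parameters, per-fold scores, objective, pruned flag).
#' @export
optimize_hyperparameters <- function(objective_fun, space, n_inner,
                                     n_trials = 200,
                                     pruning_percentile = 80,
                                     warmup = 10, n_startup = 10,
                                     seed = 1L) {
  stopifnot(n_trials >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (length(space) == 0) n_trials <- 1L
  n_startup <- min(n_startup, n_trials)
  startup <- if (length(space)) hp_startup_plan(space, n_startup)

  history <- vector("list", n_trials)
  completed_steps <- list()   # per trial: running means at each step
  best_value <- -Inf
  best_params <- list()

  for (t in seq_len(n_trials)) {
    completed <- purrr::keep(history[seq_len(t - 1)],
                             ~ !is.null(.x) && !.x$pruned && !.x$failed)
    params <- if (length(space) == 0) {
      list()
    } else if (t <= n_startup) {
      purrr::map(startup, t)
    } else if (length(completed) < 4) {
      hp_sample_uniform(space)
    } else if (stats::runif(1) < 0.25) {
      hp_sample_uniform(space)   # sustained exploration
    } else {
      objs <- vapply(completed, function(h) h$objective, 0)
      q <- stats::quantile(objs, 0.75, names = FALSE)
      good <- purrr::keep(completed, ~ .x$objective >= q)
      hp_sample_guided(space, purrr::map(good, "params"))
    }

    scores <- numeric(0)
    pruned <- FALSE
    failed <- FALSE
    fail_msg <- NA_character_
    for (j in seq_len(n_inner)) {
      sc <- tryCatch(objective_fun(params, j), error = function(e) e)
      if (inherits(sc, "error")) {
        # invalid setting (e.g. impossible architecture geometry): the trial
        # fails, the search continues
        failed <- TRUE
        fail_msg <- conditionMessage(sc)
        break
      }
      scores[j] <- sc
      run_mean <- mean(scores)
      n_done <- length(completed_steps)
      if (!is.null(pruning_percentile) && j < n_inner && n_done >= warmup) {
        ref <- vapply(completed_steps, function(s) s[j], 0)
        thr <- stats::quantile(ref, pruning_percentile / 100, names = FALSE)
        if (run_mean < thr) { pruned <- TRUE; break }
      }
    }
    objective <- if (pruned || failed) NA_real_ else mean(scores)
    if (!pruned && !failed) {
      completed_steps[[length(completed_steps) + 1]] <- cumsum(scores) / seq_along(scores)
      if (objective > best_value) {
        best_value <- objective
        best_params <- params
      }
    }
    history[[t]] <- list(trial = t, params = params, scores = scores,
                         objective = objective, pruned = pruned,
                         failed = failed, error = fail_msg)
  }
  if (!is.finite(best_value) &&
      all(vapply(history, function(h) h$failed, TRUE))) {
    last_err <- history[[n_trials]]$error
    stop("all trials failed; last error: ", last_err, call. = FALSE)
  }

  history_tbl <- tibble::tibble(
    trial = vapply(history, function(h) h$trial, 0L),
    params = purrr::map(history, "params"),
    scores = purrr::map(history, "scores"),
    n_folds_run = vapply(history, function(h) length(h$scores), 0L),
    objective = vapply(history, function(h) h$objective, 0),
    pruned = vapply(history, function(h) h$pruned, TRUE),
    failed = vapply(history, function(h) h$failed, TRUE))

  list(best_params = best_params, best_value = best_value,
       history = history_tbl)
}

# ---- experiment runner ------------------------------------------------------

# encode a genotype panel for one model; returns the full-sample matrix
encode_for_model <- function(G, model) {
  if (model$encoding == "onehot") {
    onehot_tensor(G)
  } else {
    encode_genotypes(G, model$encoding)$values
  }
}

# standardize columns using statistics from the training rows only
standardize_split <- function(X, train_idx) {
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sd <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sd, `/`)
}

#' Run the benchmarking experiment
#'
#' For each requested model and each outer fold: tune hyperparameters on
#' the five inner folds (mean inner explained variance as the objective,
#' with percentile pruning), refit on the full outer-training data with
#' the best setting, and score the hold-out test fold with
#' [explained_variance()]. Encodings follow each model's contract;
#' standardization statistics, where a model requires them, are computed
#' on training rows only. Per-fold feature importances are recorded for
#' the models that define them. Model-level failures are caught and
#' recorded; the experiment continues.
#'
#' @param G a `gs_genotypes` panel.
#' @param y named phenotype vector aligned with (a subset of) the panel's
#'   samples.
#' @param models character vector of model names (see [gs_model_names()]),
#'   or `"all"`.
#' @param n_trials hyperparameter trial budget per outer fold.
#' @param n_outer,n_inner,n_bins split-plan settings.
#' @param pruning_percentile see [optimize_hyperparameters()].
#' @param seed integer master seed (splits and per-trial seeds derive from
#'   it).
#' @param phenotype_name label recorded in the results.
#' @param model_opts extra arguments passed to [gs_model()] (chain/epoch
#'   settings).
#' @return A `gs_evaluation` object: tibble `results` (one row per model
#'   and outer fold), `summary` (mean and sd of v per model),
#'   `importances` (per model, per-fold importance vectors), `plan`,
#'   `trial_histories`, `errors`, and run metadata.
#' @export
run_experiment <- function(G, y, models = c("rrblup", "elasticnet"),
                           n_trials = 50, n_outer = 3, n_inner = 5,
                           n_bins = 10, pruning_percentile = 80,
                           seed = 1L, phenotype_name = "phenotype",
                           model_opts = list()) {
  stopifnot(inherits(G, "gs_genotypes"))
  if (identical(models, "all")) models <- gs_model_names()
  models <- match.arg(models, gs_model_names(), several.ok = TRUE)
  if (is.null(names(y))) {
    stopifnot(length(y) == nrow(G$values))
    names(y) <- G$sample_ids
  }
  keep <- match(names(y), G$sample_ids)
  if (anyNA(keep))
    stop("phenotype sample ids missing from the genotype panel: ",
         names(y)[is.na(keep)][1], call. = FALSE)
  G <- G[keep, ]

  plan <- stratified_nested_splits(y, n_outer, n_inner, n_bins, seed = seed)
  all_idx <- seq_along(y)

  results <- list(); importances <- list(); histories <- list()
  errors <- list()
  for (mi in seq_along(models)) {
    mname <- models[mi]
    model <- do.call(gs_model, c(list(name = mname), model_opts))
    enc <- tryCatch(encode_for_model(G, model), error = function(e) e)
    if (inherits(enc, "error")) {
      errors[[mname]] <- conditionMessage(enc)
      next
    }
    fold_rows <- list(); fold_imps <- list()
    for (k in seq_len(n_outer)) {
      res <- tryCatch({
        test <- plan$outer[[k]]
        train_full <- setdiff(all_idx, test)
        inner_folds <- plan$inner[[k]]
        trial_counter <- 0L
        objective_fun <- function(params, j) {
          val <- inner_folds[[j]]
          tr <- setdiff(train_full, val)
          Xj <- if (model$standardize) standardize_split(enc, tr) else enc
          trial_counter <<- trial_counter + 1L
          fit_seed <- (seed * 10000L + mi * 1000L + k * 100L + trial_counter) %% .Machine$integer.max
          fit <- model$fit(Xj[tr, , drop = FALSE], y[tr], params, fit_seed)
          explained_variance(y[val], stats::predict(fit, Xj[val, , drop = FALSE]))
        }
        opt <- optimize_hyperparameters(
          objective_fun, model$search_space, n_inner = n_inner,
          n_trials = n_trials, pruning_percentile = pruning_percentile,
          seed = (seed * 131L + mi * 17L + k) %% .Machine$integer.max)
        Xk <- if (model$standardize) standardize_split(enc, train_full) else enc
        refit_seed <- (seed * 10000L + mi * 1000L + k * 100L + 99L) %% .Machine$integer.max
        fit <- model$fit(Xk[train_full, , drop = FALSE], y[train_full],
                         opt$best_params, refit_seed)
        v <- explained_variance(y[test], stats::predict(fit, Xk[test, , drop = FALSE]))
        imp <- if (mname %in% gs_importance_models()) {
          iv <- gs_importance(fit)
          names(iv) <- G$marker_ids
          iv
        } else NULL
        list(v = v, params = opt$best_params, history = opt$history, imp = imp)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste0(mname, "_fold", k)]] <- conditionMessage(res)
        fold_rows[[k]] <- tibble::tibble(
          model = mname, phenotype = phenotype_name, fold = k,
          v = NA_real_, best_params = list(NULL))
      } else {
        fold_rows[[k]] <- tibble::tibble(
          model = mname, phenotype = phenotype_name, fold = k,
          v = res$v, best_params = list(res$params))
        histories[[paste0(mname, "_fold", k)]] <- res$history
        if (!is.null(res$imp)) fold_imps[[k]] <- res$imp
      }
    }
    results[[mname]] <- dplyr::bind_rows(fold_rows)
    if (length(fold_imps)) importances[[mname]] <- fold_imps
  }

  results_tbl <- dplyr::bind_rows(results)
  summary_tbl <- results_tbl |>
    dplyr::group_by(.data$model, .data$phenotype) |>
    dplyr::summarise(v_mean = mean(.data$v), v_sd = stats::sd(.data$v),
                     .groups = "drop")
  structure(
    list(results = results_tbl, summary = summary_tbl,
         importances = importances, plan = plan,
         trial_histories = histories, errors = errors,
         settings = list(models = models, n_trials = n_trials,
                         n_outer = n_outer, n_inner = n_inner,
                         n_bins = n_bins,
                         pruning_percentile = pruning_percentile,
                         seed = as.integer(seed),
                         phenotype = phenotype_name)),
    class = "gs_evaluation")
}

#' @export
print.gs_evaluation <- function(x, ...) {
  cat(sprintf("<gs_evaluation> %s: %d model(s), %d outer folds, %d trials\n",
              x$settings$phenotype, length(x$settings$models),
              x$settings$n_outer, x$settings$n_trials))
  print(x$summary)
  if (length(x$errors))
    cat("errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Tabular + graphical heatmap of evaluation results
#'
#' Builds the models-by-phenotypes table of mean explained variance (with
#' a companion standard-deviation table), writes both as CSV when a path
#' is given, and returns a ggplot heatmap with the best model per
#' phenotype highlighted.
#'
#' @param results a `gs_evaluation`, a list of them, or a tibble with
#'   columns `model`, `phenotype`, `v_mean`, `v_sd`.
#' @param path optional output stem; writes `<path>_mean.csv`,
#'   `<path>_sd.csv` and `<path>.png`.
#' @return list with `mean_table`, `sd_table` (tibbles, models as rows)
#'   and `plot`.
#' @export
results_heatmap <- function(results, path = NULL) {
  tbl <- if (inherits(results, "gs_evaluation")) {
    results$summary
  } else if (is.data.frame(results)) {
    results
  } else {
    dplyr::bind_rows(purrr::map(results, "summary"))
  }
  stopifnot(all(c("model", "phenotype", "v_mean") %in% names(tbl)))
  mean_tbl <- tbl |>
    dplyr::select("model", "phenotype", "v_mean") |>
    tidyr::pivot_wider(names_from = "phenotype", values_from = "v_mean")
  sd_tbl <- tbl |>
    dplyr::select("model", "phenotype", "v_sd") |>
    tidyr::pivot_wider(names_from = "phenotype", values_from = "v_sd")
  best <- tbl |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::slice_max(.data$v_mean, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$model, y = .data$phenotype,
                                         fill = .data$v_mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = best, fill = NA, colour = "black",
                       linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$v_mean)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", midpoint = 0.5,
                                  limits = c(NA, 1), name = "v") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Explained variance by model and phenotype") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    readr::write_csv(mean_tbl, paste0(path, "_mean.csv"))
    readr::write_csv(sd_tbl, paste0(path, "_sd.csv"))
    ggplot2::ggsave(paste0(path, ".png"), p, width = 7, height = 4, dpi = 150)
  }
  list(mean_table = mean_tbl, sd_table = sd_tbl, plot = p)
}
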