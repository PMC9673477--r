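#' Hyperparameter space primitives
#'
#' A search space is a list of parameter descriptors: uniform real,
#' log-uniform real, integer or categorical, each with finite bounds or an
#' explicit choice set.
#'
#' @param name parameter name.
#' @param low,high bounds (finite; positive for `hp_logreal`).
#' @param choices vector of categorical choices.
#' @export
hp_real <- function(name, low, high) {
  stopifnot(is.finite(low), is.finite(high), low < high)
  list(name = name, type = "real", low = low, high = high)
}
#' @rdname hp_real
#' @export
hp_logreal <- function(name, low, high) {
  stopifnot(low > 0, high > low, is.finite(high))
  list(name = name, type = "logreal", low = low, high = high)
}
#' @rdname hp_real
#' @export
hp_int <- function(name, low, high) {
  stopifnot(low <= high)
  list(name = name, type = "int", low = as.integer(low), high = as.integer(high))
}
#' @rdname hp_real
#' @export
hp_cat <- function(name, choices) {
  stopifnot(length(choices) >= 1)
  list(name = name, type = "categorical", choices = choices)
}

#' Model roster
#'
#' @return Character vector of the twelve supported model names.
#' @export
gs_model_names <- function() {
  c("rrblup", "bayesA", "bayesB", "bayesC", "lasso", "elasticnet",
    "svr", "rf", "xgb", "mlp", "cnn", "lcnn")
}

#' Construct a prediction model under the uniform contract
#'
#' Every model exposes the same surface: an `encoding` requirement
#' (`additive012` by default, `additive_centered` for RR-BLUP, `onehot`
#' for CNN/LCNN), whether its inputs are standardized per marker
#' (SVR and the MLP), a hyperparameter `search_space`, and
#' `fit(X, y, params, seed)` returning a fitted object that supports
#' `predict()`. Models without tunable hyperparameters (RR-BLUP, the
#' Bayesian alphabet) carry an empty search space and the harness runs a
#' single trial for them.
#'
#' @param name one of [gs_model_names()].
#' @param bayes_iter,bayes_burn_in chain settings used by the Bayesian
#'   models (scaled down from the reference 6000/1000 when desk-scale
#'   runtimes matter).
#' @param nn_epochs,nn_patience training-length settings for the neural
#'   models.
#' @return A `gs_model` object.
#' @export
gs_model <- function(name, bayes_iter = 1500, bayes_burn_in = 300,
                     nn_epochs = 100, nn_patience = 10) {
  name <- match.arg(name, gs_model_names())
  enc <- switch(name, rrblup = "additive_centered",
                cnn = , lcnn = "onehot", "additive012")
  std <- name %in% c("svr", "mlp")
  space <- switch(name,
    rrblup = , bayesA = , bayesB = , bayesC = list(),
    lasso = list(hp_logreal("alpha", 1e-3, 1e3)),
    elasticnet = list(hp_logreal("alpha", 1e-3, 1e3),
                      hp_real("l1_ratio", 0.01, 1)),
    svr = list(hp_logreal("C", 1e-2, 1e3),
               hp_real("epsilon_frac", 0.01, 1),
               hp_cat("kernel", c("linear", "rbf"))),
    rf = list(hp_int("num_trees", 100, 1000),
              hp_int("max_depth", 2, 20),
              hp_real("mtry_fraction", 0.1, 1)),
    xgb = list(hp_int("nrounds", 50, 1000),
               hp_logreal("eta", 1e-3, 0.3),
               hp_int("max_depth", 2, 10),
               hp_real("subsample", 0.5, 1)),
    mlp = list(hp_int("n_blocks", 1, 4),
               hp_cat("units", c(32L, 64L, 128L, 256L, 512L, 1024L)),
               hp_real("dropout", 0, 0.5),
               hp_logreal("learning_rate", 1e-4, 1e-2),
               hp_cat("activation", c("relu", "tanh"))),
    cnn = list(hp_int("n_blocks", 1, 3),
               hp_int("filters", 4, 16),
               hp_int("kernel_size", 3, 9),
               hp_int("stride", 1, 3),
               hp_cat("units", c(32L, 64L, 128L)),
               hp_real("dropout", 0, 0.5),
               hp_logreal("learning_rate", 1e-4, 1e-2),
               hp_cat("activation", c("relu", "tanh"))),
    lcnn = list(hp_int("n_blocks", 1, 3),
                hp_int("filters", 2, 8),
                hp_int("kernel_size", 3, 9),
                hp_int("stride", 2, 5),
                hp_cat("units", c(32L, 64L, 128L)),
                hp_real("dropout", 0, 0.5),
                hp_logreal("learning_rate", 1e-4, 1e-2),
                hp_cat("activation", c("relu", "tanh"))))
  fit_fun <- switch(name,
    rrblup = function(X, y, params, seed) fit_rrblup(X, y),
    bayesA = function(X, y, params, seed)
      fit_bayes(X, y, "A", n_iter = bayes_iter, burn_in = bayes_burn_in, seed = seed),
    bayesB = function(X, y, params, seed)
      fit_bayes(X, y, "B", n_iter = bayes_iter, burn_in = bayes_burn_in, seed = seed),
    bayesC = function(X, y, params, seed)
      fit_bayes(X, y, "C", n_iter = bayes_iter, burn_in = bayes_burn_in, seed = seed),
    lasso = function(X, y, params, seed)
      fit_penalized_linear(X, y, alpha = params$alpha, l1_ratio = 1),
    elasticnet = function(X, y, params, seed)
      fit_penalized_linear(X, y, alpha = params$alpha, l1_ratio = params$l1_ratio),
    svr = function(X, y, params, seed)
      fit_svr(X, y, kernel = params$kernel, C = params$C,
              tube_epsilon = params$epsilon_frac * stats::sd(y)),
    rf = function(X, y, params, seed)
      fit_rf(X, y, num_trees = params$num_trees, max_depth = params$max_depth,
             mtry_fraction = params$mtry_fraction, seed = seed),
    xgb = function(X, y, params, seed)
      fit_xgb(X, y, nrounds = params$nrounds, eta = params$eta,
              max_depth = params$max_depth, subsample = params$subsample,
              seed = seed),
    mlp = function(X, y, params, seed)
      fit_nn(nn_architecture("mlp", n_blocks = params$n_blocks,
                             units = params$units, dropout = params$dropout,
                             activation = params$activation,
                             learning_rate = params$learning_rate,
                             epochs = nn_epochs, patience = nn_patience),
             X, y, channels = 1, seed = seed),
    cnn = function(X, y, params, seed)
      fit_nn(nn_architecture("cnn", n_blocks = params$n_blocks,
                             filters = params$filters,
                             kernel_size = params$kernel_size,
                             stride = params$stride, units = params$units,
                             dropout = params$dropout,
                             activation = params$activation,
                             learning_rate = params$learning_rate,
                             epochs = nn_epochs, patience = nn_patience),
             X, y, channels = 3, seed = seed),
    lcnn = function(X, y, params, seed)
      fit_nn(nn_architecture("lcnn", n_blocks = params$n_blocks,
                             filters = params$filters,
                             kernel_size = params$kernel_size,
                             stride = params$stride, units = params$units,
                             dropout = params$dropout,
                             activation = params$activation,
                             learning_rate = params$learning_rate,
                             epochs = nn_epochs, patience = nn_patience),
             X, y, channels = 3, seed = seed))
  structure(list(name = name, encoding = enc, standardize = std,
                 channels = if (enc == "onehot") 3L else 1L,
                 search_space = space, fit = fit_fun),
            class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cat(sprintf("<gs_model> %s (encoding %s%s), %d tunable hyperparameters\n",
              x$name, x$encoding,
              if (x$standardize) ", standardized" else "",
              length(x$search_space)))
  invisible(x)
}

#' Per-marker feature importance of a fitted model
#'
#' Returns the importance vector used by the downstream analysis:
#' absolute coefficient magnitudes for the linear and Bayesian models
#' (signed values remain available on the fit object), normalized impurity
#' or gain reduction for the tree ensembles. Models without a defined
#' per-marker importance (SVR, the neural networks and any one-hot model)
#' raise an error.
#'
#' @param fit a fitted model object produced by a `gs_model`'s `fit`.
#' @return Named numeric vector, one value per marker.
#' @export
gs_importance <- function(fit) {
  if (inherits(fit, "gs_rrblup")) return(abs(fit$w))
  if (inherits(fit, "gs_bayes"))
    return(stats::setNames(abs(fit$posterior_mean_w),
                           fit$marker_ids))
  if (inherits(fit, "gs_penalized")) return(abs(fit$w))
  if (inherits(fit, "gs_rf")) return(fit$importance)
  if (inherits(fit, "gs_xgb")) return(fit$importance)
  stop("feature importance is not defined for models of class ",
       paste(class(fit), collapse = "/"), call. = FALSE)
}

#' Which models expose feature importances
#' @export
gs_importance_models <- function() {
  c("rrblup", "bayesB", "lasso", "elasticnet", "rf", "xgb")
}
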