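#' Support vector regression (epsilon-insensitive)
#'
#' Thin wrapper over the libsvm epsilon-SVR solver (via e1071). The model
#' fits a function staying within a tube of half-width `tube_epsilon`
#' around the targets, with slack penalized at rate `C`; larger `C` puts
#' more weight on fitting errors, smaller `C` on flatness of the decision
#' function.
#'
#' @param X numeric matrix.
#' @param y numeric response.
#' @param kernel `"linear"`, `"rbf"` or `"polynomial"`.
#' @param C penalty weight (> 0).
#' @param tube_epsilon half-width of the insensitivity tube (>= 0). Note:
#'   this is the SVR tube, not the simulator's residual noise.
#' @param gamma RBF/polynomial kernel coefficient (default `1/ncol(X)`).
#' @param degree polynomial degree.
#' @return A `gs_svr` object.
#' @export
fit_svr <- function(X, y, kernel = c("rbf", "linear", "polynomial"),
                    C = 1, tube_epsilon = 0.1,
                    gamma = NULL, degree = 3, tolerance = 0.01) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), C > 0, tube_epsilon >= 0)
  svm_kernel <- switch(kernel, rbf = "radial", linear = "linear",
                       polynomial = "polynomial")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  fit <- tryCatch(
    e1071::svm(x = X, y = y, type = "eps-regression",
               kernel = svm_kernel, cost = C, epsilon = tube_epsilon,
               gamma = gamma, degree = degree, scale = FALSE,
               tolerance = tolerance),
    error = function(e) {
      # a tube wider than the spread of y leaves no support vectors: the
      # flat solution (w = 0) is optimal and the fit is a constant
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
      else stop(e)
    })
  structure(list(fit = fit, kernel = kernel, C = C,
                 tube_epsilon = tube_epsilon,
                 constant = if (is.null(fit)) mean(y) else NULL),
            class = "gs_svr")
}

#' @export
predict.gs_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(object$fit)) return(rep(object$constant, nrow(newdata)))
  as.numeric(stats::predict(object$fit, newdata))
}

#' Random forest regression
#'
#' Bagged regression trees (via ranger); the prediction is the mean over
#' the ensemble. Impurity-based feature importances are exposed,
#' normalized to sum to one.
#'
#' @param X numeric matrix.
#' @param y numeric response.
#' @param num_trees number of trees.
#' @param max_depth maximum tree depth (0 = unlimited).
#' @param mtry_fraction fraction of markers tried per split.
#' @param min_node_size minimal node size.
#' @param seed integer seed (forests are reproducible for a fixed seed).
#' @export
fit_rf <- function(X, y, num_trees = 500, max_depth = 0,
                   mtry_fraction = 0.3, min_node_size = 5, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, max.depth = max_depth,
    mtry = max(1L, floor(mtry_fraction * ncol(X))),
    min.node.size = min_node_size,
    importance = "impurity", seed = as.integer(seed),
    num.threads = 1, verbose = FALSE)
  imp <- fit$variable.importance
  s <- sum(imp)
  structure(list(fit = fit,
                 importance = if (s > 0) imp / s else imp),
            class = "gs_rf")
}

#' @export
predict.gs_rf <- function(object, newdata, ...) {
  nd <- as.data.frame(as.matrix(newdata), check.names = FALSE)
  as.numeric(stats::predict(object$fit, data = nd,
                            num.threads = 1, verbose = FALSE)$predictions)
}

#' Gradient-boosted trees
#'
#' Sequentially added regression trees guided by the loss gradient (via
#' xgboost). Gain-based feature importances are exposed, normalized to sum
#' to one over markers (zero for markers never used in a split).
#'
#' @param X numeric matrix.
#' @param y numeric response.
#' @param nrounds number of boosting rounds.
#' @param eta learning rate.
#' @param max_depth maximum tree depth.
#' @param subsample row subsampling rate per round.
#' @param colsample colsample_bytree.
#' @param seed integer seed.
#' @export
fit_xgb <- function(X, y, nrounds = 200, eta = 0.1, max_depth = 4,
                    subsample = 1, colsample = 1, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fit <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = eta,
                  max_depth = max_depth, subsample = subsample,
                  colsample_bytree = colsample, nthread = 1,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0)
  imp_tab <- tryCatch(xgboost::xgb.importance(model = fit),
                      error = function(e) NULL)
  imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp_tab) && nrow(imp_tab) > 0)
    imp[imp_tab$Feature] <- imp_tab$Gain
  s <- sum(imp)
  structure(list(fit = fit, feature_names = colnames(X),
                 importance = if (s > 0) imp / s else imp),
            class = "gs_xgb")
}

#' @export
predict.gs_xgb <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  colnames(nd) <- object$feature_names
  as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(nd)))
}
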