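#' Fit RR-BLUP (ridge-regression BLUP) by restricted maximum likelihood
#'
#' Fits the marker mixed model `y = mu 1 + X w + e` with
#' `w ~ N(0, sigma2_g I_m)` and `e ~ N(0, sigma2_e I_n)`. The variance
#' components maximize the restricted likelihood, profiled over the
#' shrinkage ratio `lambda = sigma2_e / sigma2_g` after a spectral
#' decomposition of the marker cross-product kernel `K = X X'` (the
#' genomic relationship kernel up to scaling, which makes the model
#' equivalent to GBLUP). The profiled REML criterion is maximized by
#' one-dimensional optimization over `log(lambda)` on `[1e-5, 1e5]`.
#'
#' Marker effects are the BLUPs `w = X'(K + lambda I)^{-1}(y - mu 1)` and
#' `mu` is the generalized-least-squares intercept.
#'
#' @param X numeric matrix of encoded genotypes (centered -1/0/1 encoding
#'   recommended), rows = samples.
#' @param y numeric response, `length(y) == nrow(X)`.
#' @param lambda optional fixed shrinkage ratio; skips REML when supplied.
#' @param lambda_bounds search interval for `lambda` under REML.
#' @return A `gs_rrblup` object with elements `mu`, `w`, `sigma2_g`,
#'   `sigma2_e`, `lambda`, `reml_loglik`, plus the training data needed for
#'   kernel-form prediction.
#' @export
fit_rrblup <- function(X, y, lambda = NULL, lambda_bounds = c(1e-5, 1e5)) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (!all(is.finite(y))) stop("non-finite phenotype values", call. = FALSE)
  colvar <- apply(X, 2, stats::var)
  if (all(colvar == 0)) stop("all marker columns are constant", call. = FALSE)

  K <- tcrossprod(X)                       # n x n marker kernel
  if (is.null(lambda)) {
    # REML: eigen-decompose the projected kernel SKS, S = I - 11'/n
    Kc <- sweep(K, 1, colMeans(K))
    Kc <- sweep(Kc, 2, rowMeans(K))
    Kc <- Kc + mean(K)
    es <- eigen(Kc, symmetric = TRUE)
    # drop the null direction of the projection (smallest eigenvalue ~ 0)
    xi <- pmax(es$values[seq_len(n - 1)], 0)
    eta <- as.numeric(crossprod(es$vectors[, seq_len(n - 1)], y - mean(y)))
    neg_restricted_ll <- function(log_lambda) {
      d <- xi + exp(log_lambda)
      s2 <- sum(eta^2 / d) / (n - 1)
      0.5 * ((n - 1) * log(s2) + sum(log(d)))
    }
    opt <- stats::optimize(neg_restricted_ll,
                           interval = log(lambda_bounds), tol = 1e-8)
    lambda <- exp(opt$minimum)
    sigma2_g <- sum(eta^2 / (xi + lambda)) / (n - 1)
    reml_ll <- -opt$objective
  } else {
    stopifnot(lambda > 0)
    sigma2_g <- NA_real_
    reml_ll <- NA_real_
  }

  H <- K + diag(lambda, n)
  Hinv_y <- solve(H, y)
  Hinv_1 <- solve(H, rep(1, n))
  mu <- sum(Hinv_y) / sum(Hinv_1)
  resid <- y - mu
  alpha <- solve(H, resid)                 # (K + lambda I)^{-1} (y - mu 1)
  w <- as.numeric(crossprod(X, alpha))
  if (is.na(sigma2_g)) {
    # with lambda fixed, estimate the genetic scale from the quadratic form
    sigma2_g <- as.numeric(crossprod(resid, alpha)) / (n - 1)
  }
  structure(
    list(mu = mu, w = stats::setNames(w, colnames(X)),
         sigma2_g = sigma2_g, sigma2_e = lambda * sigma2_g,
         lambda = lambda, reml_loglik = reml_ll,
         alpha = alpha, X_train = X),
    class = "gs_rrblup")
}

#' Predict from an RR-BLUP fit
#'
#' `form = "marker"` uses the marker effects (`mu + X_new w`);
#' `form = "kernel"` uses the GBLUP kernel form
#' (`mu + X_new X_train' (K + lambda I)^{-1} (y - mu 1)`). The two are
#' algebraically identical.
#'
#' @param object a `gs_rrblup` fit.
#' @param newdata encoded matrix with the same columns as the training data.
#' @param form `"marker"` or `"kernel"`.
#' @param ... unused.
#' @export
predict.gs_rrblup <- function(object, newdata, form = c("marker", "kernel"), ...) {
  form <- match.arg(form)
  newdata <- as.matrix(newdata)
  if (form == "marker") {
    as.numeric(object$mu + newdata %*% object$w)
  } else {
    Knew <- tcrossprod(newdata, object$X_train)
    as.numeric(object$mu + Knew %*% object$alpha)
  }
}

#' @export
print.gs_rrblup <- function(x, ...) {
  cat(sprintf("<gs_rrblup> %d markers, lambda=%.4g (sigma2_g=%.4g, sigma2_e=%.4g)\n",
              length(x$w), x$lambda, x$sigma2_g, x$sigma2_e))
  invisible(x)
}

#' Ridge closed form with a fixed penalty (reference solver)
#'
#' Direct dense solution of `(X'X + lambda I) w = X'(y - mu 1)` with the
#' GLS intercept, used as an independent check of the kernel-form BLUP at a
#' fixed `lambda`.
#'
#' @inheritParams fit_rrblup
#' @keywords internal
#' @export
ridge_closed_form <- function(X, y, lambda) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  H <- tcrossprod(X) + diag(lambda, n)
  Hinv_1 <- solve(H, rep(1, n))
  mu <- sum(solve(H, y)) / sum(Hinv_1)
  w <- solve(crossprod(X) + diag(lambda, m), crossprod(X, y - mu))
  list(mu = mu, w = as.numeric(w))
}
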