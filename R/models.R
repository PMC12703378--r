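# standardisation helpers (fitted on calibration rows only)
fit_standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
apply_standardizer <- function(std, X)
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")

#' Epsilon-SVR with RBF kernel and grid-searched hyperparameters
#'
#' Support vector regression with a radial basis function kernel. Inputs
#' are standardised (centred and scaled by calibration statistics). The
#' cost `c` and kernel width `g` are chosen by exhaustive grid search
#' scored with `cv_folds`-fold RMSECV on deterministic interleaved folds;
#' ties go to the first grid point in iteration order, so the fit is fully
#' reproducible. The quadratic-programming core is delegated to
#' [e1071::svm()].
#'
#' @param X calibration matrix (samples x variables).
#' @param y calibration response.
#' @param c_grid,g_grid candidate cost and RBF-gamma values; defaults
#'   `2^(-8..8)` (17 log-spaced points each).
#' @param epsilon epsilon-tube half width; default `0.01 * sd(y)`.
#' @param cv_folds folds for the grid search (default 5).
#' @return an object of class `svm_model` holding the refitted model at
#'   the best `(c, g)`, the standardisation constants and the RMSECV grid.
#'   A constant `y` yields a constant predictor with a warning.
#' @export
svm_fit <- function(X, y, c_grid = 2^(-8:8), g_grid = 2^(-8:8),
                    epsilon = NULL, cv_folds = 5L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!length(c_grid) || !length(g_grid)) stop("empty hyperparameter grid")
  if (stats::sd(y) == 0) {
    warning("constant response: returning a constant predictor")
    return(structure(list(constant = y[1L]), class = "svm_model"))
  }
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  epsilon <- epsilon %||% (0.01 * stats::sd(y))
  n <- nrow(Xs)
  fold <- venetian_folds(n, cv_folds)
  grid_rmse <- matrix(NA_real_, length(c_grid), length(g_grid),
                      dimnames = list(format(c_grid), format(g_grid)))
  best <- list(rmse = Inf)
  for (ci in seq_along(c_grid)) for (gi in seq_along(g_grid)) {
    sse <- 0
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
                      type = "eps-regression", kernel = "radial",
                      cost = c_grid[ci], gamma = g_grid[gi],
                      epsilon = epsilon, scale = FALSE)
      pr <- stats::predict(m, Xs[!tr, , drop = FALSE])
      sse <- sse + sum((y[!tr] - pr)^2)
    }
    grid_rmse[ci, gi] <- sqrt(sse / n)
    if (grid_rmse[ci, gi] < best$rmse)
      best <- list(rmse = grid_rmse[ci, gi], cost = c_grid[ci],
                   gamma = g_grid[gi])
  }
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    cost = best$cost, gamma = best$gamma,
                    epsilon = epsilon, scale = FALSE)
  structure(list(fit = fit, standardizer = std, cost = best$cost,
                 gamma = best$gamma, epsilon = epsilon,
                 rmsecv_grid = grid_rmse,
                 fitted = as.numeric(stats::predict(fit, Xs))),
            class = "svm_model")
}

#' @rdname svm_fit
#' @param object a fitted `svm_model`.
#' @param newdata matrix with the columns the model was fitted on.
#' @param ... unused.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  as.numeric(stats::predict(object$fit,
                            apply_standardizer(object$standardizer, newdata)))
}

#' Extreme learning machine regression
#'
#' Single-hidden-layer network with random, untrained input weights:
#' `W` (inputs x hidden) and biases `b` are drawn uniformly from
#' `[-1, 1]` using the mandatory seed, the hidden activations are
#' `H = act(X_std W + b)`, and the output weights are the analytic
#' least-norm solution `beta = pinv(H) y` (Moore-Penrose pseudo-inverse
#' via [MASS::ginv()]). Inputs are standardised by calibration statistics.
#' Deterministic given the seed.
#'
#' @param X calibration matrix.
#' @param y calibration response.
#' @param n_hidden number of hidden neurons (default 50, must be >= 1).
#' @param activation `"sigmoid"` (default) or `"identity"`.
#' @param seed RNG seed for the input weights (mandatory).
#' @return an object of class `elm_model`.
#' @export
elm_fit <- function(X, y, n_hidden = 50L, activation = c("sigmoid",
                                                         "identity"),
                    seed) {
  X <- as.matrix(X); y <- as.numeric(y)
  activation <- match.arg(activation)
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 1L) stop("n_hidden must be >= 1")
  if (missing(seed)) stop("seed is mandatory for elm_fit()")
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  p <- ncol(Xs)
  rnd <- with_seed(seed, list(
    W = matrix(stats::runif(p * n_hidden, -1, 1), p, n_hidden),
    b = stats::runif(n_hidden, -1, 1)))
  H <- elm_hidden(Xs, rnd$W, rnd$b, activation)
  beta <- MASS::ginv(H) %*% y
  structure(list(W = rnd$W, b = rnd$b, beta = beta, activation = activation,
                 standardizer = std, seed = seed,
                 fitted = as.numeric(H %*% beta)),
            class = "elm_model")
}

elm_hidden <- function(Xs, W, b, activation) {
  A <- sweep(Xs %*% W, 2L, b, "+")
  if (activation == "sigmoid") 1 / (1 + exp(-A)) else A
}

#' @rdname elm_fit
#' @param object a fitted `elm_model`.
#' @param newdata matrix with the columns the model was fitted on.
#' @param ... unused.
#' @export
predict.elm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- apply_standardizer(object$standardizer, newdata)
  H <- elm_hidden(Xs, object$W, object$b, object$activation)
  as.numeric(H %*% object$beta)
}
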