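# NIPALS PLS1 core. For a single response the NIPALS weight vector has the
# closed form w = X'y / ||X'y||, so each latent variable costs a few
# matrix-vector products plus one rank-1 deflation. The coefficient path
# B_k = W (P'W)^{-1} q_{1..k} is accumulated by forward substitution
# (P'W is unit upper triangular for NIPALS).
nipals_pls1 <- function(X, y, n_lv) {
  n <- nrow(X); p <- ncol(X)
  n_lv <- min(n_lv, n - 1L, p)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  W <- P <- R <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  Bpath <- matrix(0, p, n_lv)
  b <- numeric(p)
  h_used <- 0L
  for (h in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(y^2)))) break  # residual exhausted
    w <- w / nw
    t <- (Xc %*% w)[, 1L]
    tt <- sum(t^2)
    if (tt < .Machine$double.eps) break
    ph <- crossprod(Xc, t)[, 1L] / tt
    qh <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, ph)
    yc <- yc - t * qh
    r <- w
    if (h > 1L) {
      prev <- seq_len(h - 1L)
      r <- w - R[, prev, drop = FALSE] %*%
        crossprod(P[, prev, drop = FALSE], w)
    }
    W[, h] <- w; P[, h] <- ph; R[, h] <- r
    Tm[, h] <- t; q[h] <- qh
    b <- b + as.numeric(r) * qh
    Bpath[, h] <- b
    h_used <- h
  }
  if (h_used == 0L) stop("PLS failed: X carries no covariance with y")
  keep <- seq_len(h_used)
  list(n_lv = h_used, x_mean = x_mean, y_mean = y_mean,
       weights = W[, keep, drop = FALSE], loadings = P[, keep, drop = FALSE],
       scores = Tm[, keep, drop = FALSE], q = q[keep],
       coef_path = Bpath[, keep, drop = FALSE])
}

# prediction matrix (n x n_lv) for the whole LV path
pls_path_predict <- function(fit, Xnew) {
  Xc <- sweep(Xnew, 2L, fit$x_mean)
  Xc %*% fit$coef_path + fit$y_mean
}

# k-fold RMSECV per number of latent variables (venetian-blind folds)
pls_cv_rmse <- function(X, y, max_lv, cv_folds) {
  n <- nrow(X)
  fold <- venetian_folds(n, cv_folds)
  max_lv <- min(max_lv, ncol(X), n - ceiling(n / cv_folds) - 1L)
  if (max_lv < 1L) stop("too few samples for the requested CV")
  sse <- numeric(max_lv)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    fit <- nipals_pls1(X[tr, , drop = FALSE], y[tr], max_lv)
    pred <- pls_path_predict(fit, X[!tr, , drop = FALSE])
    # folds that exhaust the residual early reuse their last LV's prediction
    res <- (y[!tr] - pred[, pmin(seq_len(max_lv), fit$n_lv), drop = FALSE])^2
    sse <- sse + colSums(res)
  }
  sqrt(sse / n)
}

#' Partial least squares regression (NIPALS)
#'
#' PLS1 regression via the NIPALS algorithm on column-centred data (no
#' scaling, the chemometric convention for spectra). The number of latent
#' variables is chosen to minimise k-fold cross-validated RMSE over
#' `1..max_lv`, with deterministic interleaved ("venetian blind") folds, so
#' the whole fit is reproducible without a seed.
#'
#' @param X numeric calibration matrix, samples x variables.
#' @param y numeric response, one value per row of `X`.
#' @param max_lv maximum number of latent variables considered (default
#'   20); must be `<= min(nrow(X) - 1, ncol(X))`.
#' @param cv_folds folds for RMSECV-based selection of the number of
#'   latent variables (default 5); `n_lv = max_lv` is used directly when
#'   `cv_folds < 2`.
#' @return an object of class `plsr_model` with elements `n_lv`,
#'   `coefficients`, `intercept`, `scores`, `loadings`, `weights`,
#'   `rmsecv` (the per-LV trace) and `fitted`.
#' @seealso [predict.plsr_model()]
#' @export
plsr_fit <- function(X, y, max_lv = 20L, cv_folds = 5L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("y has zero variance")
  if (max_lv < 1L || max_lv > min(n - 1L, p))
    stop("max_lv must lie in [1, min(n - 1, p)]")
  rmsecv <- NULL
  n_lv <- max_lv
  if (cv_folds >= 2L) {
    rmsecv <- pls_cv_rmse(X, y, max_lv, cv_folds)
    n_lv <- which.min(rmsecv)
  }
  fit <- nipals_pls1(X, y, n_lv)
  coef <- fit$coef_path[, fit$n_lv]
  intercept <- fit$y_mean - sum(fit$x_mean * coef)
  structure(list(n_lv = fit$n_lv, coefficients = coef,
                 intercept = intercept, x_mean = fit$x_mean,
                 y_mean = fit$y_mean, scores = fit$scores,
                 loadings = fit$loadings, weights = fit$weights,
                 rmsecv = rmsecv,
                 fitted = as.numeric(X %*% coef + intercept)),
            class = "plsr_model")
}

#' @rdname plsr_fit
#' @param object a fitted `plsr_model`.
#' @param newdata matrix with the same columns the model was fitted on.
#' @param ... unused.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata has ", ncol(newdata), " columns, model expects ",
         length(object$coefficients))
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variables, %d predictors\n",
              x$n_lv, length(x$coefficients)))
  invisible(x)
}
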