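# wavelength selection: SPA, UVE, CARS -----------------------------------

new_selection_result <- function(method, selected, wavelengths, diagnostics,
                                 best_run = NULL) {
  selected <- sort(unique(as.integer(selected)))
  structure(list(method = method, selected_indices = selected,
                 selected_nm = wavelengths[selected],
                 diagnostics = diagnostics, best_run = best_run),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d variables", toupper(x$method),
              length(x$selected_indices)))
  if (length(x$selected_nm))
    cat(sprintf(" (%.1f-%.1f nm)", min(x$selected_nm), max(x$selected_nm)))
  if (!is.null(x$best_run)) cat(sprintf(", best run %d", x$best_run))
  cat("\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Writes the selected indices, their wavelengths and the method
#' diagnostics (UVE stability trace, CARS RMSECV / variable-count paths,
#' SPA size-vs-RMSE curve) so selection figures can be regenerated outside R.
#'
#' @param sr a `selection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(sr, path) {
  jsonlite::write_json(unclass(sr), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Successive projections algorithm
#'
#' Forward selection that minimises collinearity: starting from each
#' candidate wavelength, a chain of up to `max_vars` variables is grown by
#' repeatedly picking the column with the largest norm after orthogonal
#' projection onto the complement of the span of the columns already in
#' the chain. Every chain prefix is then scored by the RMSE of a multiple
#' linear regression on an internal rank-stratified validation split of the
#' calibration samples, and the (start, size) combination with minimal
#' validation RMSE wins. Deterministic: the internal split is the
#' [gradient_split()] of `y`, so no seed is involved.
#'
#' @param X calibration spectra matrix (samples x wavelengths), typically
#'   already preprocessed.
#' @param y calibration reference values.
#' @param max_vars chain length cap (default 30); must be
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @param wavelengths optional wavelength grid for reporting (defaults to
#'   column indices).
#' @param starts optional subset of starting columns (defaults to all).
#' @return a `selection_result`; `diagnostics` holds the winning start and
#'   its RMSE-vs-size trace.
#' @references Araujo et al. (2001) Chemometr. Intell. Lab. 57, 65-73.
#' @export
spa_select <- function(X, y, max_vars = 30L, wavelengths = NULL,
                       starts = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (stats::sd(y) == 0) stop("y has zero variance")
  if (max_vars > min(n - 1L, p))
    stop("max_vars must be <= min(n_samples - 1, n_wavelengths)")
  wavelengths <- wavelengths %||% seq_len(p)
  starts <- starts %||% seq_len(p)
  sp <- gradient_split(y)
  tr <- sp$calibration; va <- sp$prediction
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]; yva <- y[va]
  max_size <- min(max_vars, length(tr) - 1L)
  norms2_0 <- colSums(Xtr^2)
  tol <- 1e-12 * max(norms2_0)
  best <- list(rmse = Inf)
  rmse_trace <- function(chain) {
    out <- rep(NA_real_, length(chain))
    for (k in seq_along(chain)) {
      idx <- chain[seq_len(k)]
      f <- stats::.lm.fit(cbind(1, Xtr[, idx, drop = FALSE]), ytr)
      pr <- cbind(1, X[va, idx, drop = FALSE]) %*% f$coefficients
      out[k] <- rmse(yva, pr)
    }
    out
  }
  for (s0 in starts) {
    if (norms2_0[s0] <= tol) next
    chain <- integer(max_size)
    chain[1L] <- s0
    Q <- matrix(0, length(tr), max_size)  # orthonormal basis of the chain
    Q[, 1L] <- Xtr[, s0] / sqrt(norms2_0[s0])
    norms2 <- norms2_0
    len <- 1L
    while (len < max_size) {
      cproj <- crossprod(Q[, len], Xtr)[1L, ]
      norms2 <- pmax(norms2 - cproj^2, 0)
      norms2[chain[seq_len(len)]] <- -1
      nxt <- which.max(norms2)
      if (norms2[nxt] <= tol) break     # span exhausted (duplicates etc.)
      v <- Xtr[, nxt] -
        Q[, seq_len(len), drop = FALSE] %*%
        crossprod(Q[, seq_len(len), drop = FALSE], Xtr[, nxt])
      nv <- sqrt(sum(v^2))
      if (nv^2 <= tol) break
      len <- len + 1L
      chain[len] <- nxt
      Q[, len] <- v / nv
    }
    chain <- chain[seq_len(len)]
    rt <- rmse_trace(chain)
    k_best <- which.min(rt)
    if (rt[k_best] < best$rmse)
      best <- list(rmse = rt[k_best], start = s0, size = k_best,
                   chain = chain, rmse_by_size = rt)
  }
  if (!is.finite(best$rmse)) stop("SPA found no usable starting variable")
  new_selection_result(
    "spa", best$chain[seq_len(best$size)], wavelengths,
    diagnostics = list(best_start = best$start, best_size = best$size,
                       chain = best$chain, rmse_by_size = best$rmse_by_size,
                       validation_rmse = best$rmse))
}

# chain oracle hook: grow a single SPA chain (used by tests against an
# independent Gram-Schmidt deflation implementation)
spa_chain <- function(X, start, max_vars) {
  X <- as.matrix(X)
  norms2_0 <- colSums(X^2)
  tol <- 1e-12 * max(norms2_0)
  chain <- integer(max_vars); chain[1L] <- start
  Q <- matrix(0, nrow(X), max_vars)
  Q[, 1L] <- X[, start] / sqrt(norms2_0[start])
  norms2 <- norms2_0
  len <- 1L
  while (len < max_vars) {
    cproj <- crossprod(Q[, len], X)[1L, ]
    norms2 <- pmax(norms2 - cproj^2, 0)
    norms2[chain[seq_len(len)]] <- -1
    nxt <- which.max(norms2)
    if (norms2[nxt] <= tol) break
    v <- X[, nxt] - Q[, seq_len(len), drop = FALSE] %*%
      crossprod(Q[, seq_len(len), drop = FALSE], X[, nxt])
    nv <- sqrt(sum(v^2))
    if (nv^2 <= tol) break
    len <- len + 1L
    chain[len] <- nxt
    Q[, len] <- v / nv
  }
  chain[seq_len(len)]
}

#' Uninformative variable elimination (UVE-PLS)
#'
#' Appends an artificial noise matrix (uniform on `[0, noise_scale]`, same
#' column count as `X`), runs leave-one-out PLS with `n_lv` components on
#' the augmented matrix, and computes the per-variable stability
#' `t_j = mean(b_j) / sd(b_j)` of the regression coefficients across
#' folds. Real variables whose `|t|` exceeds `threshold_factor` times the
#' maximum `|t|` among the noise columns are retained; everything less
#' stable than artificial noise is deemed uninformative.
#'
#' @param X calibration spectra matrix.
#' @param y calibration reference values.
#' @param n_lv number of PLS components for the coefficient fits
#'   (default 10, internally capped by the fold size).
#' @param noise_scale amplitude of the artificial noise; default
#'   `1e-10 * max(abs(X))`, the classic tiny-noise convention.
#' @param threshold_factor multiplier on the noise-ceiling `|t|`
#'   (default 0.99). `Inf` retains nothing; `0` retains everything.
#' @param wavelengths optional wavelength grid for reporting.
#' @param seed RNG seed for the noise matrix (mandatory).
#' @return a `selection_result`; `diagnostics` holds the full stability
#'   trace (real then noise columns) and the threshold. The selection may
#'   be empty when no variable beats the noise ceiling.
#' @references Centner et al. (1996) Anal. Chem. 68, 3851-3858.
#' @export
uve_select <- function(X, y, n_lv = 10L, noise_scale = NULL,
                       threshold_factor = 0.99, wavelengths = NULL,
                       seed) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 5L) stop("UVE needs at least 5 samples (leave-one-out PLS)")
  if (n_lv < 1L) stop("n_lv must be >= 1")
  if (missing(seed)) stop("seed is mandatory for uve_select()")
  wavelengths <- wavelengths %||% seq_len(p)
  noise_scale <- noise_scale %||% (1e-10 * max(abs(X)))
  N <- with_seed(seed, matrix(stats::runif(n * p, 0, noise_scale), n, p))
  Z <- cbind(X, N)
  nlv_use <- min(n_lv, n - 2L, ncol(Z))
  B <- matrix(0, n, 2L * p)
  for (i in seq_len(n)) {
    fit <- nipals_pls1(Z[-i, , drop = FALSE], y[-i], nlv_use)
    B[i, ] <- fit$coef_path[, fit$n_lv]
  }
  bm <- colMeans(B)
  bs <- apply(B, 2L, stats::sd)
  tstab <- bm / bs
  degen <- bs == 0
  if (any(degen)) {
    warning(sum(degen), " coefficient(s) with zero fold variance; ",
            "stability set to +/-Inf (degenerate run)")
    tstab[degen] <- sign(bm[degen]) * Inf
    tstab[degen & bm == 0] <- 0
  }
  noise_ceiling <- max(abs(tstab[(p + 1L):(2L * p)]))
  threshold <- threshold_factor * noise_ceiling
  keep <- which(abs(tstab[seq_len(p)]) > threshold)
  new_selection_result(
    "uve", keep, wavelengths,
    diagnostics = list(stability = tstab, threshold = threshold,
                       noise_ceiling = noise_ceiling, n_lv = nlv_use,
                       noise_scale = noise_scale))
}

#' CARS exponentially decreasing retention schedule
#'
#' Closed form of the enforced-reduction ratio `r_i = a * exp(-k * i)`
#' fixed by `r_1 = 1` and `r_(n_runs) = 2/p`:
#' `k = log(p / 2) / (n_runs - 1)`, `a = exp(k)`.
#'
#' @param p number of variables at run 0 (full set).
#' @param n_runs number of sampling runs.
#' @return list with `a`, `k` and the ratio vector `ratio` (length
#'   `n_runs`).
#' @export
cars_schedule <- function(p, n_runs) {
  stopifnot(p >= 3, n_runs >= 2)
  k <- log(p / 2) / (n_runs - 1)
  a <- exp(k)
  list(a = a, k = k, ratio = a * exp(-k * seq_len(n_runs)))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo wavelength selection: at each of `n_runs` sampling runs a
#' PLS model is fitted on a random `sample_fraction` of the calibration
#' samples using the currently retained variables; normalised absolute
#' regression coefficients `w_j = |b_j| / sum|b_j|` act as fitness
#' weights. The retained count follows the exponentially decreasing
#' schedule of [cars_schedule()] (never below 2): an enforced reduction
#' first discards everything outside the top `2 m_i` weights, then
#' adaptive reweighted sampling draws exactly `m_i` variables without
#' replacement with probability proportional to the weights. Each run's
#' subset is scored by `cv_folds`-fold RMSECV (deterministic interleaved
#' folds); the run with minimal RMSECV defines the selected subset.
#'
#' @param X calibration spectra matrix (`>= 3` columns).
#' @param y calibration reference values.
#' @param n_runs number of sampling runs (default 100).
#' @param cv_folds folds for the per-run RMSECV (default 5).
#' @param sample_fraction fraction of calibration samples used for each
#'   run's coefficient fit (default 0.8).
#' @param n_lv PLS components for the coefficient fits and RMSECV
#'   (default 10, capped by subset size).
#' @param wavelengths optional wavelength grid for reporting.
#' @param seed RNG seed for the Monte-Carlo sampling (mandatory).
#' @return a `selection_result` with `best_run` and diagnostics `rmsecv`
#'   (length `n_runs`), `n_retained`, `ratio`, the per-run retained sets
#'   and the per-run coefficient path.
#' @references Li et al. (2009) Anal. Chim. Acta 648, 77-84.
#' @export
cars_select <- function(X, y, n_runs = 100L, cv_folds = 5L,
                        sample_fraction = 0.8, n_lv = 10L,
                        wavelengths = NULL, seed) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 3L) stop("CARS needs at least 3 variables")
  if (n_runs < 2L) stop("n_runs must be >= 2")
  if (missing(seed)) stop("seed is mandatory for cars_select()")
  wavelengths <- wavelengths %||% seq_len(p)
  sched <- cars_schedule(p, n_runs)
  n_sub <- max(2L, round(sample_fraction * n))
  rmsecv <- numeric(n_runs)
  n_ret <- integer(n_runs)
  sets <- vector("list", n_runs)
  coef_path <- vector("list", n_runs)
  with_seed(seed, {
    retained <- seq_len(p)
    m_prev <- p
    for (i in seq_len(n_runs)) {
      sub <- sample.int(n, n_sub)
      fit <- nipals_pls1(X[sub, retained, drop = FALSE], y[sub],
                         min(n_lv, length(retained), n_sub - 1L))
      b <- fit$coef_path[, fit$n_lv]
      w <- abs(b)
      if (sum(w) == 0) w <- rep(1, length(w)) else w <- w / sum(w)
      m_i <- max(2L, min(m_prev, as.integer(round(sched$ratio[i] * p))))
      # enforced reduction: competition restricted to the top weights
      ord <- order(w, decreasing = TRUE)
      cand <- ord[seq_len(min(length(retained), 2L * m_i))]
      pick <- if (length(cand) == m_i) cand
      else cand[sample.int(length(cand), m_i,
                           prob = pmax(w[cand], 1e-300))]
      coef_path[[i]] <- stats::setNames(b, retained)
      retained <- sort(retained[pick])
      m_prev <- m_i
      n_ret[i] <- length(retained)
      rmsecv[i] <- min(pls_cv_rmse(X[, retained, drop = FALSE], y,
                                   min(n_lv, length(retained)), cv_folds))
      sets[[i]] <- retained
    }
  })
  best_run <- which.min(rmsecv)
  new_selection_result(
    "cars", sets[[best_run]], wavelengths,
    diagnostics = list(rmsecv = rmsecv, n_retained = n_ret,
                       ratio = sched$ratio, schedule = sched[c("a", "k")],
                       retained_sets = sets, coef_path = coef_path),
    best_run = best_run)
}
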