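#' First derivative of spectra
#'
#' Grid-aware finite differences: central differences at interior points of
#' the (possibly non-uniform) wavelength grid, one-sided differences at the
#' two endpoints. With `scale = TRUE` (default) the result is dR/d(lambda)
#' in 1/nm; with `scale = FALSE` plain differences over one/two grid steps
#' are returned.
#'
#' @param s a [spectra_set()] with at least 3 wavelengths.
#' @param scale divide by the wavelength spacing (default `TRUE`).
#' @return a `spectra_set` on the unchanged grid.
#' @export
first_derivative <- function(s, scale = TRUE) {
  p <- n_wavelengths(s)
  if (p < 3L) stop("first_derivative needs at least 3 wavelengths")
  wl <- s$wavelengths
  hi <- c(2:p, p)
  lo <- c(1L, 1:(p - 1L))
  num <- s$reflectance[, hi, drop = FALSE] - s$reflectance[, lo, drop = FALSE]
  den <- if (scale) wl[hi] - wl[lo] else (hi - lo)
  spectra_set(sweep(num, 2L, den, "/"), wl, s$sample_ids, s$metadata)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing: each spectrum is convolved with the
#' Savitzky-Golay kernel for the given window and polynomial order; the
#' first and last half-windows are handled by the off-centre rows of the
#' same local polynomial fit, so polynomials of degree <= `polyorder` are
#' reproduced exactly everywhere.
#'
#' @param s a [spectra_set()].
#' @param window odd window length in points, `> polyorder` and
#'   `<= n_wavelengths(s)`.
#' @param polyorder degree of the local polynomial (default 2).
#' @return a smoothed `spectra_set` on the unchanged grid.
#' @export
savitzky_golay <- function(s, window = 11L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > n_wavelengths(s))
    stop("window exceeds the number of wavelengths")
  sm <- t(apply(s$reflectance, 1L, signal::sgolayfilt,
                p = polyorder, n = window))
  spectra_set(sm, s$wavelengths, s$sample_ids, s$metadata)
}

#' Standard normal variate transform
#'
#' Per-spectrum autoscaling: each spectrum is centred to mean zero and
#' scaled to unit standard deviation (n-1 denominator), removing
#' multiplicative gain and additive offset differences between scans.
#'
#' @param s a [spectra_set()]; every spectrum must have nonzero variance.
#' @return the transformed `spectra_set`.
#' @export
snv <- function(s) {
  m <- rowMeans(s$reflectance)
  ctr <- s$reflectance - m
  sdv <- sqrt(rowSums(ctr^2) / (n_wavelengths(s) - 1L))
  zero <- which(sdv == 0)
  if (length(zero))
    stop("zero-variance spectrum, SNV undefined for sample(s): ",
         paste(s$sample_ids[zero], collapse = ", "))
  spectra_set(ctr / sdv, s$wavelengths, s$sample_ids, s$metadata)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on a reference spectrum by ordinary least
#' squares, `x ~ b0 + b1 * ref`, and corrected to `(x - b0) / b1`. The
#' reference is the column-wise mean of the calibration spectra and, once
#' fitted, is frozen: prediction spectra are corrected against the
#' calibration reference, never their own mean.
#'
#' @param calib calibration [spectra_set()] used to fit the reference
#'   spectrum, or a numeric reference spectrum of matching length.
#' @param apply_to spectra to correct (defaults to `calib`).
#' @param tol singular-slope tolerance; `|b1|` below it is an error.
#' @return the corrected `spectra_set`, with the fitted reference attached
#'   as attribute `"msc_reference"`.
#' @export
msc_fit_apply <- function(calib, apply_to = calib, tol = 1e-10) {
  ref <- if (inherits(calib, "spectra_set")) {
    if (n_samples(calib) < 1L) stop("empty calibration set")
    colMeans(calib$reflectance)
  } else as.numeric(calib)
  if (length(ref) != n_wavelengths(apply_to))
    stop("reference spectrum length does not match the wavelength grid")
  ref_c <- ref - mean(ref)
  ss_ref <- sum(ref_c^2)
  if (ss_ref == 0) stop("constant reference spectrum, MSC undefined")
  X <- apply_to$reflectance
  b1 <- (X %*% ref_c)[, 1L] / ss_ref          # OLS slope against ref
  b0 <- rowMeans(X) - b1 * mean(ref)
  bad <- which(abs(b1) < tol)
  if (length(bad))
    stop("MSC slope below tolerance for sample(s): ",
         paste(apply_to$sample_ids[bad], collapse = ", "))
  out <- spectra_set((X - b0) / b1, apply_to$wavelengths,
                     apply_to$sample_ids, apply_to$metadata)
  attr(out, "msc_reference") <- ref
  out
}

# ---- composable pretreatment chains -----------------------------------------

PREPROCESS_NAMES <- c("raw", "fd", "sg", "fd+sg", "msc", "snv")

#' Pretreatment chains
#'
#' A `preprocess_chain` is an ordered list of transform steps applied
#' left-to-right. Steps are referred to by the fixed names `raw`, `fd`,
#' `sg`, `fd+sg`, `msc`, `snv`; `fd+sg` expands to the first derivative
#' followed by Savitzky-Golay smoothing. Parameters (SG window/order, FD
#' scaling) may be attached per step. Chains with an `msc` step must be
#' fitted on calibration spectra with [fit_preprocess()] before they can be
#' applied to new spectra: the MSC reference spectrum is estimated from the
#' calibration set only and then frozen.
#'
#' @param ... step names (characters) and/or lists of the form
#'   `list(name = "sg", window = 11, polyorder = 2)`.
#' @return an object of class `preprocess_chain`.
#' @examples
#' preprocess_chain("snv")
#' preprocess_chain("fd+sg")
#' preprocess_chain(list(name = "sg", window = 7, polyorder = 3), "snv")
#' @export
preprocess_chain <- function(...) {
  raw_steps <- list(...)
  if (length(raw_steps) == 1L && is.list(raw_steps[[1L]]) &&
      is.null(raw_steps[[1L]]$name))
    raw_steps <- raw_steps[[1L]]  # allow a single list of steps
  steps <- list()
  for (st in raw_steps) {
    if (is.character(st)) st <- list(name = st)
    if (is.null(st$name) || !st$name %in% PREPROCESS_NAMES)
      stop("unknown preprocessing step: ",
           deparse(st$name %||% st), "; valid names: ",
           paste(PREPROCESS_NAMES, collapse = ", "))
    if (st$name == "fd+sg") {  # expand the combined treatment, FD first
      steps <- c(steps, list(list(name = "fd", scale = st$scale %||% TRUE)))
      st <- list(name = "sg", window = st$window %||% 11L,
                 polyorder = st$polyorder %||% 2L)
    }
    if (st$name == "raw") next
    steps <- c(steps, list(st))
  }
  structure(list(steps = steps), class = "preprocess_chain")
}

as_chain <- function(x) {
  if (inherits(x, "preprocess_chain")) x
  else if (is.character(x)) do.call(preprocess_chain, as.list(x))
  else preprocess_chain(x)
}

apply_step <- function(st, s) {
  switch(st$name,
         fd  = first_derivative(s, scale = st$scale %||% TRUE),
         sg  = savitzky_golay(s, window = st$window %||% 11L,
                              polyorder = st$polyorder %||% 2L),
         snv = snv(s),
         msc = {
           if (is.null(st$reference))
             stop("msc step has no fitted reference; call fit_preprocess()")
           msc_fit_apply(st$reference, s)
         },
         stop("unknown step ", st$name))
}

#' @rdname preprocess_chain
#' @param chain a `preprocess_chain` (or a character vector of step names).
#' @param calib calibration [spectra_set()]; fit-dependent steps (MSC) learn
#'   their state here.
#' @return [fit_preprocess()] returns a `fitted_preprocess` object.
#' @export
fit_preprocess <- function(chain, calib) {
  chain <- as_chain(chain)
  cur <- calib
  steps <- chain$steps
  for (k in seq_along(steps)) {
    if (steps[[k]]$name == "msc")
      steps[[k]]$reference <- colMeans(cur$reflectance)
    cur <- apply_step(steps[[k]], cur)
  }
  structure(list(steps = steps, wavelengths = calib$wavelengths),
            class = "fitted_preprocess")
}

#' @rdname preprocess_chain
#' @param fitted a `fitted_preprocess` object.
#' @param s spectra to transform; must share the grid the chain was fitted on.
#' @return [apply_preprocess()] returns the transformed `spectra_set`.
#' @export
apply_preprocess <- function(fitted, s) {
  if (!inherits(fitted, "fitted_preprocess"))
    stop("fitted must come from fit_preprocess()")
  if (!isTRUE(all.equal(fitted$wavelengths, s$wavelengths)))
    stop("wavelength grid differs from the grid the chain was fitted on")
  for (st in fitted$steps) s <- apply_step(st, s)
  s
}
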