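#' Fit a full calibration pipeline
#'
#' Chains the workflow stages for one target parameter: fit the
#' pretreatment chain on the calibration spectra, transform them, run the
#' wavelength selector on the calibration rows only, and fit the
#' calibration model on the selected columns. Everything fitted (MSC
#' reference, standardisation constants, selected indices, model) derives
#' exclusively from calibration rows; prediction spectra are only ever
#' transformed with the frozen state via [predict.calibration_pipeline()].
#'
#' @param spectra a [spectra_set()] holding calibration (and possibly
#'   prediction) samples.
#' @param y reference values, one per row of `spectra`.
#' @param calibration indices or sample ids of the calibration rows.
#' @param chain pretreatment chain name(s) or [preprocess_chain()]
#'   (default `"snv"`).
#' @param selector `"full"`, `"spa"`, `"uve"` or `"cars"`.
#' @param model `"plsr"`, `"svm"` or `"elm"`.
#' @param selector_args,model_args extra arguments for the selector /
#'   model fit.
#' @param seed seed forwarded to stochastic stages (UVE noise, CARS
#'   sampling, ELM weights).
#' @param selection optional precomputed `selection_result` (or integer
#'   index vector) to reuse, e.g. when several models share one selector
#'   run; the selector stage is then skipped.
#' @return an object of class `calibration_pipeline`.
#' @export
fit_pipeline <- function(spectra, y, calibration,
                         chain = "snv", selector = "full", model = "plsr",
                         selector_args = list(), model_args = list(),
                         seed = 1L, selection = NULL) {
  selector <- match.arg(selector, c("full", "spa", "uve", "cars"))
  model <- match.arg(model, c("plsr", "svm", "elm"))
  if (is.character(calibration)) {
    calibration <- match(calibration, spectra$sample_ids)
    if (anyNA(calibration)) stop("unknown calibration sample ids")
  }
  calib_s <- subset_samples(spectra, calibration)
  y_cal <- y[calibration]
  fitted_chain <- fit_preprocess(as_chain(chain), calib_s)
  Xc <- apply_preprocess(fitted_chain, calib_s)$reflectance
  wl <- spectra$wavelengths
  if (is.null(selection) && selector != "full")
    selection <- switch(
      selector,
      spa  = do.call(spa_select,
                     c(list(X = Xc, y = y_cal, wavelengths = wl),
                       selector_args)),
      uve  = do.call(uve_select,
                     c(list(X = Xc, y = y_cal, wavelengths = wl,
                            seed = seed), selector_args)),
      cars = do.call(cars_select,
                     c(list(X = Xc, y = y_cal, wavelengths = wl,
                            seed = seed), selector_args)))
  sel_idx <- if (is.null(selection)) seq_len(ncol(Xc))
  else if (inherits(selection, "selection_result"))
    selection$selected_indices
  else sort(unique(as.integer(selection)))
  if (length(sel_idx) == 0L)
    stop("selector '", selector, "' retained no variables")
  Xsel <- Xc[, sel_idx, drop = FALSE]
  fit <- switch(
    model,
    plsr = do.call(plsr_fit, c(list(
      X = Xsel, y = y_cal,
      max_lv = min(model_args$max_lv %||% 20L,
                   nrow(Xsel) - 1L, ncol(Xsel))),
      model_args[setdiff(names(model_args), "max_lv")])),
    svm  = do.call(svm_fit, c(list(X = Xsel, y = y_cal), model_args)),
    elm  = do.call(elm_fit, c(list(X = Xsel, y = y_cal, seed = seed),
                              model_args)))
  structure(list(chain = fitted_chain,
                 selection = if (inherits(selection, "selection_result"))
                   selection,
                 selected_indices = sel_idx, model_kind = model,
                 model = fit, wavelengths = wl,
                 calibration_ids = spectra$sample_ids[calibration],
                 seed = seed),
            class = "calibration_pipeline")
}

#' @rdname fit_pipeline
#' @param object a fitted `calibration_pipeline`.
#' @param newdata a [spectra_set()] on the same wavelength grid the
#'   pipeline was fitted on.
#' @param ... unused.
#' @return predictions, one per row of `newdata`, named by sample id.
#' @export
predict.calibration_pipeline <- function(object, newdata, ...) {
  if (!inherits(newdata, "spectra_set"))
    stop("newdata must be a spectra_set")
  if (!isTRUE(all.equal(object$wavelengths, newdata$wavelengths)))
    stop("wavelength grid mismatch: pipeline was fitted on a different grid")
  Xp <- apply_preprocess(object$chain, newdata)$reflectance
  pred <- predict(object$model,
                  Xp[, object$selected_indices, drop = FALSE])
  stats::setNames(as.numeric(pred), newdata$sample_ids)
}

#' @export
print.calibration_pipeline <- function(x, ...) {
  sel <- if (is.null(x$selection)) "full spectrum"
  else sprintf("%s (%d vars)", x$selection$method,
               length(x$selected_indices))
  cat(sprintf("<calibration_pipeline> %s, %s, %d calibration samples\n",
              sel, x$model_kind, length(x$calibration_ids)))
  invisible(x)
}
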