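#' Spectra container
#'
#' A `spectra_set` bundles a reflectance matrix with its wavelength grid and
#' per-sample metadata. Rows are samples (or replicate scans), columns are
#' wavelengths in nm on a strictly increasing, possibly non-uniform grid.
#' Reflectance is dimensionless, typically in (0, 1], but any positive unit
#' is accepted.
#'
#' @param reflectance numeric matrix, samples x wavelengths.
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm);
#'   length must equal `ncol(reflectance)`.
#' @param sample_ids unique character labels, one per row. Defaults to
#'   rownames of `reflectance`, or `S001`, `S002`, ... when absent.
#' @param metadata optional `data.frame` with one row per sample; recognised
#'   columns are `storage_day`, `temperature` and `replicate_group`.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `wavelengths`, `reflectance`, `sample_ids` and `metadata`.
#' @examples
#' s <- spectra_set(matrix(runif(12), 3), wavelengths = c(500, 600, 700, 800))
#' n_samples(s)
#' @export
spectra_set <- function(reflectance, wavelengths,
                        sample_ids = NULL, metadata = NULL) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(reflectance) %||%
      sprintf("S%03d", seq_len(nrow(reflectance)))
  }
  sample_ids <- as.character(sample_ids)
  obj <- structure(
    list(wavelengths = wavelengths, reflectance = reflectance,
         sample_ids = sample_ids, metadata = metadata),
    class = "spectra_set")
  validate_spectra_set(obj)
}

validate_spectra_set <- function(x) {
  if (ncol(x$reflectance) != length(x$wavelengths))
    stop("reflectance has ", ncol(x$reflectance),
         " columns but there are ", length(x$wavelengths), " wavelengths")
  if (length(x$wavelengths) > 1 && any(diff(x$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(x$wavelengths)) stop("wavelengths contain NA")
  if (nrow(x$reflectance) != length(x$sample_ids))
    stop("sample_ids length does not match number of spectra")
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  if (!is.null(x$metadata)) {
    if (!is.data.frame(x$metadata) || nrow(x$metadata) != length(x$sample_ids))
      stop("metadata must be a data.frame with one row per sample")
  }
  rownames(x$reflectance) <- x$sample_ids
  x
}

#' @rdname spectra_set
#' @param x a `spectra_set`.
#' @export
n_samples <- function(x) nrow(x$reflectance)

#' @rdname spectra_set
#' @export
n_wavelengths <- function(x) length(x$wavelengths)

#' Subset a spectra_set by sample
#'
#' @param x a `spectra_set`.
#' @param i integer indices, logical mask, or sample ids.
#' @return a `spectra_set` containing the selected rows.
#' @export
subset_samples <- function(x, i) {
  if (is.character(i)) {
    pos <- match(i, x$sample_ids)
    if (anyNA(pos)) stop("unknown sample ids: ",
                         paste(i[is.na(pos)], collapse = ", "))
    i <- pos
  }
  spectra_set(x$reflectance[i, , drop = FALSE], x$wavelengths,
              x$sample_ids[i],
              if (!is.null(x$metadata)) x$metadata[i, , drop = FALSE])
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%.1f-%.1f nm)\n",
              n_samples(x), n_wavelengths(x),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.spectra_set <- function(x, ...) x$reflectance

#' Reference-value table
#'
#' Wet-lab reference measurements per sample: soluble solids content
#' (SSC, %), titratable acidity (TA, g/L tartaric-acid equivalents) and pH,
#' optionally with the storage condition (day, temperature in degrees C)
#' each sample was drawn from.
#'
#' @param sample_id unique sample labels.
#' @param SSC soluble solids content in percent; must be positive.
#' @param TA titratable acidity in g/L; must be positive.
#' @param pH juice pH; must lie in (0, 14).
#' @param day,temperature optional storage metadata.
#' @return a `data.frame` of class `reference_table`.
#' @export
reference_table <- function(sample_id, SSC, TA, pH,
                            day = NA_real_, temperature = NA_real_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   SSC = as.numeric(SSC), TA = as.numeric(TA),
                   pH = as.numeric(pH), day = day,
                   temperature = temperature,
                   stringsAsFactors = FALSE)
  class(df) <- c("reference_table", "data.frame")
  validate_reference_table(df)
}

validate_reference_table <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (any(!is.finite(df$SSC)) || any(df$SSC <= 0))
    stop("SSC values must be positive and finite")
  if (any(!is.finite(df$TA)) || any(df$TA <= 0))
    stop("TA values must be positive and finite")
  if (any(!is.finite(df$pH)) || any(df$pH <= 0) || any(df$pH >= 14))
    stop("pH values must lie in (0, 14)")
  df
}
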