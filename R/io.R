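#' Read a wide-format spectra CSV
#'
#' The exchange dialect is the common spectrometer-export layout: the first
#' column holds the sample id, every remaining column header is a numeric
#' wavelength in nm, and cells are reflectance values in plain decimal
#' notation. Malformed numeric cells, ragged rows, duplicate sample ids and
#' non-monotone wavelength headers are hard errors, never silently dropped.
#'
#' @param path path to a comma-separated UTF-8 file.
#' @return a [spectra_set()] with rows in file order.
#' @seealso [write_spectra_csv()] for the inverse operation.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L)
    stop("ragged CSV: rows have differing field counts (",
         paste(unique(nf), collapse = ", "), ")")
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("spectra CSV needs an id column plus wavelengths")
  ids <- df[[1L]]
  wl <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(wl))
    stop("non-numeric wavelength header(s): ",
         paste(names(df)[-1L][is.na(wl)], collapse = ", "))
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("wavelength header is not strictly increasing")
  mat <- matrix(NA_real_, nrow(df), length(wl))
  for (j in seq_along(wl)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed numeric cell at row %d, wavelength %s: '%s'",
                   bad[1L], names(df)[j + 1L], df[[j + 1L]][bad[1L]]))
    mat[, j] <- v
  }
  spectra_set(mat, wl, sample_ids = ids)
}

#' Write a spectra_set as wide-format CSV
#'
#' @param s a [spectra_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  df <- data.frame(sample_id = s$sample_ids, s$reflectance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", format(s$wavelengths, trim = TRUE,
                                     scientific = FALSE, drop0trailing = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a reference-value table
#'
#' Long-format CSV with columns `sample_id`, `SSC`, `TA`, `pH` and
#' optionally `day`, `temperature`.
#'
#' @param path CSV path.
#' @return [read_reference_csv()] returns a [reference_table()];
#'   [write_reference_csv()] returns `path` invisibly.
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "SSC", "TA", "pH")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  reference_table(df$sample_id, df$SSC, df$TA, df$pH,
                  day = df$day %||% NA_real_,
                  temperature = df$temperature %||% NA_real_)
}

#' @rdname read_reference_csv
#' @param refs a [reference_table()].
#' @export
write_reference_csv <- function(refs, path) {
  utils::write.csv(as.data.frame(refs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Truncate a spectra_set to a wavelength window
#'
#' Keeps exactly the columns whose wavelength lies in the closed interval
#' `[low_nm, high_nm]`; samples are untouched. Mirrors the usual practice of
#' discarding the noisy short-wavelength end of a Vis-NIR scan.
#'
#' @param s a [spectra_set()].
#' @param low_nm,high_nm window bounds in nm, `low_nm < high_nm`.
#' @return a `spectra_set` on the restricted grid.
#' @export
truncate_range <- function(s, low_nm, high_nm) {
  if (!(low_nm < high_nm)) stop("low_nm must be < high_nm")
  keep <- s$wavelengths >= low_nm & s$wavelengths <= high_nm
  if (!any(keep))
    stop(sprintf("no wavelengths inside [%g, %g] nm", low_nm, high_nm))
  spectra_set(s$reflectance[, keep, drop = FALSE], s$wavelengths[keep],
              s$sample_ids, s$metadata)
}

#' Average replicate scans
#'
#' Collapses replicate rows to their arithmetic mean, one output row per
#' replicate group, in first-appearance order. Groups are taken from
#' `metadata$replicate_group` unless supplied explicitly.
#'
#' @param s a [spectra_set()].
#' @param group optional character/factor vector of group labels, one per
#'   row of `s`.
#' @return a `spectra_set` with one spectrum per group; group labels become
#'   the new sample ids.
#' @export
average_replicates <- function(s, group = NULL) {
  if (is.null(group)) group <- s$metadata$replicate_group
  if (is.null(group)) stop("no replicate_group labels available")
  group <- as.character(group)
  if (length(group) != n_samples(s))
    stop("group labels must match the number of spectra")
  if (anyNA(group) || any(!nzchar(group)))
    stop("missing replicate_group label(s)")
  levels <- unique(group)  # first-appearance order
  gi <- match(group, levels)
  counts <- tabulate(gi, nbins = length(levels))
  sums <- rowsum(s$reflectance, gi, reorder = TRUE)
  avg <- sums / counts
  meta <- NULL
  if (!is.null(s$metadata)) {
    first <- match(levels, group)
    meta <- s$metadata[first, setdiff(names(s$metadata), "replicate_group"),
                       drop = FALSE]
    if (ncol(meta) == 0L) meta <- NULL else rownames(meta) <- NULL
  }
  spectra_set(avg, s$wavelengths, sample_ids = levels, metadata = meta)
}
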