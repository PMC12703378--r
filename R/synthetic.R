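#' Simulation configuration for synthetic grape spectra
#'
#' Defines the generative model for a spectra-plus-references dataset with
#' the statistical structure the downstream calibration workflow assumes:
#' a fixed reflectance background with the characteristic Vis-NIR features
#' of white table grapes (peaks near 530-630, 720 and 810 nm, absorption
#' valleys near 670 and 970 nm), analyte-linked Gaussian absorption bands,
#' a smooth polynomial baseline, per-scan multiplicative/additive scatter,
#' and white noise. Planted band positions are recorded as ground truth so
#' wavelength selectors can be validated.
#'
#' @param n_samples number of samples (default 145, a storage-trial scale).
#' @param wavelength_start_nm,wavelength_end_nm,wavelength_step_nm uniform
#'   wavelength grid in nm (default 400-1100 by 0.5, i.e. 1401 points).
#' @param band_specs `data.frame` with columns `center` (nm), `width`
#'   (Gaussian sd, nm), `parameter` (one of `SSC`, `TA`, `pH`) and
#'   `coefficient` (reflectance change per parameter unit at the band
#'   centre; negative = absorption). See Details for the defaults.
#' @param scatter_gain_range interval for the per-scan multiplicative gain.
#' @param scatter_offset_sd sd of the per-scan additive offset
#'   (reflectance units).
#' @param baseline_poly_coeffs polynomial baseline coefficients `c0, c1,
#'   ...` evaluated in the rescaled wavelength `u in [0, 1]`.
#' @param noise_sd sd of additive white noise per point (reflectance
#'   units); also used as the replicate-scan noise.
#' @param reference_ranges `data.frame` with columns `parameter`, `min`,
#'   `max`, `mean`, `sd`, `trend`: target distribution of the reference
#'   values and the signed fractional storage trend (fraction of the mean
#'   reached at the warmest temperature on the last storage day).
#' @param storage_design `data.frame` with columns `temperature` (deg C)
#'   and `day`; samples are assigned to its rows cyclically.
#' @param n_replicates scans per sample (default 1); replicate rows share
#'   the deterministic spectrum and differ by scatter and noise.
#' @param seed RNG seed governing the whole dataset.
#'
#' @details
#' Default planted bands: SSC at 970 nm (carbohydrate/water O-H overtone
#' region) and 840 nm; TA at 890 and 1040 nm; pH a single broad, weak band
#' at 1010 nm with a lower coefficient, so the pH analogue is intentionally
#' the hardest target. Default reference distributions follow a typical
#' white-grape storage trial: SSC 9.23-22.73 % (mean 17.35, sd 2.30), TA
#' 3.87-9.79 g/L (mean 5.92, sd 1.46), pH 3.06-4.59 (mean 3.82, sd 0.20),
#' with SSC drifting up and TA down over 15 days, fastest at the warmest
#' of three storage temperatures (2.7, 10.0, 20.6 deg C).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 145L,
                       wavelength_start_nm = 400,
                       wavelength_end_nm = 1100,
                       wavelength_step_nm = 0.5,
                       band_specs = default_band_specs(),
                       scatter_gain_range = c(0.9, 1.1),
                       scatter_offset_sd = 0.01,
                       baseline_poly_coeffs = c(0, 0.01),
                       noise_sd = 0.002,
                       reference_ranges = default_reference_ranges(),
                       storage_design = default_storage_design(),
                       n_replicates = 1L,
                       seed = 1L) {
  cfg <- structure(
    list(n_samples = as.integer(n_samples),
         wavelength_start_nm = wavelength_start_nm,
         wavelength_end_nm = wavelength_end_nm,
         wavelength_step_nm = wavelength_step_nm,
         band_specs = band_specs,
         scatter_gain_range = sort(as.numeric(scatter_gain_range)),
         scatter_offset_sd = scatter_offset_sd,
         baseline_poly_coeffs = baseline_poly_coeffs,
         noise_sd = noise_sd,
         reference_ranges = reference_ranges,
         storage_design = storage_design,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 8L) stop("n_samples must be at least 8")
  wl <- config_wavelengths(cfg)
  if (length(wl) < 2L || any(diff(wl) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$scatter_offset_sd < 0) stop("scatter_offset_sd must be >= 0")
  if (any(cfg$scatter_gain_range <= 0)) stop("gains must be positive")
  bs <- cfg$band_specs
  need <- c("center", "width", "parameter", "coefficient")
  if (!all(need %in% names(bs)))
    stop("band_specs needs columns ", paste(need, collapse = ", "))
  if (any(bs$center < min(wl) | bs$center > max(wl)))
    stop("band center(s) outside the wavelength grid: ",
         paste(bs$center[bs$center < min(wl) | bs$center > max(wl)],
               collapse = ", "))
  if (any(bs$width <= 0)) stop("band widths must be positive")
  rr <- cfg$reference_ranges
  if (!all(c("parameter", "min", "max", "mean", "sd") %in% names(rr)))
    stop("reference_ranges needs parameter/min/max/mean/sd columns")
  if (any(rr$min >= rr$max)) stop("reference min must be < max")
  if (any(rr$sd < 0)) stop("reference sd must be >= 0")
  if (!all(bs$parameter %in% rr$parameter))
    stop("band_specs reference unknown parameter(s)")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  sd_ <- cfg$storage_design
  if (!all(c("temperature", "day") %in% names(sd_)))
    stop("storage_design needs temperature and day columns")
  cfg
}

config_wavelengths <- function(cfg)
  seq(cfg$wavelength_start_nm, cfg$wavelength_end_nm,
      by = cfg$wavelength_step_nm)

#' @rdname sim_config
#' @export
default_band_specs <- function() {
  data.frame(
    center      = c(970,    840,    890,    1040,   1010),
    width       = c(30,     20,     20,     20,     50),
    parameter   = c("SSC",  "SSC",  "TA",   "TA",   "pH"),
    coefficient = -c(0.0030, 0.0020, 0.0045, 0.0035, 0.0080),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_reference_ranges <- function() {
  data.frame(
    parameter = c("SSC", "TA", "pH"),
    min   = c(9.23,  3.87, 3.06),
    max   = c(22.73, 9.79, 4.59),
    mean  = c(17.35, 5.92, 3.82),
    sd    = c(2.30,  1.46, 0.20),
    trend = c(0.10, -0.10, 0.02),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_storage_design <- function() {
  data.frame(temperature = rep(c(2.7, 10.0, 20.6), each = 6L),
             day = rep(c(0, 3, 6, 9, 12, 15), times = 3L))
}

# signed, standardised storage score: day fraction x temperature weight
storage_score <- function(day, temperature) {
  s <- rep(0, length(day))
  if (max(day) > 0) {
    tspan <- diff(range(temperature))
    tw <- if (tspan > 0) (temperature - min(temperature)) / tspan else 1
    s <- (day / max(day)) * tw
  }
  if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else rep(0, length(s))
}

#' Generate reference values
#'
#' Draws per-sample SSC, TA and pH from truncated normal distributions with
#' the configured mean and sd, clipped to the configured (min, max), and
#' superimposes a monotone storage trend: part of the dispersion budget is
#' carried by a standardised day-by-temperature score (signed per
#' parameter), so values correlate with the storage metadata; the remainder
#' is an independent truncated-normal draw. The trend share is derived from
#' `reference_ranges$trend` (fraction of the mean reached at the warmest
#' temperature on the final day) and capped at 0.9 of the sd. With `sd = 0`
#' the distribution is degenerate at the mean. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [reference_table()] with storage metadata.
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  des <- config$storage_design
  cell <- ((seq_len(n) - 1L) %% nrow(des)) + 1L
  day <- des$day[cell]
  temp <- des$temperature[cell]
  u <- storage_score(day, temp)
  rr <- config$reference_ranges
  vals <- with_seed(config$seed, {
    out <- list()
    for (k in seq_len(nrow(rr))) {
      mu <- rr$mean[k]; sdv <- rr$sd[k]
      lo <- rr$min[k]; hi <- rr$max[k]
      if (sdv == 0) { out[[rr$parameter[k]]] <- rep(mu, n); next }
      trend <- rr$trend[k] %||% 0
      amp <- abs(trend) * mu                       # target shift at day-15/warmest
      umax <- max(abs(u), 1e-12)
      rho <- min(0.9, amp / (sdv * umax))
      # inverse-CDF truncated normal for the residual component
      pa <- stats::pnorm((lo - mu) / sdv)
      pb <- stats::pnorm((hi - mu) / sdv)
      z <- stats::qnorm(pa + stats::runif(n) * (pb - pa))
      v <- mu + sdv * (sign(trend) * rho * u + sqrt(1 - rho^2) * z)
      out[[rr$parameter[k]]] <- pmin(pmax(v, lo), hi)
    }
    out
  })
  reference_table(sprintf("S%03d", seq_len(n)),
                  SSC = vals$SSC, TA = vals$TA, pH = vals$pH,
                  day = day, temperature = temp)
}

#' Fixed background reflectance of a white-grape spectrum
#'
#' The deterministic, analyte-independent part of the synthetic spectra:
#' a smooth curve with reflectance peaks near 580 (yellow-green skin
#' colour), 720 and 810 nm and absorption valleys near 670 nm (chlorophyll/
#' carotenoid region) and 970 nm (water/carbohydrate O-H region).
#'
#' @param wavelengths numeric vector of wavelengths in nm.
#' @return reflectance values in (0, 1).
#' @export
grape_background <- function(wavelengths) {
  g <- function(c, w) exp(-(wavelengths - c)^2 / (2 * w^2))
  0.30 + 0.20 * g(580, 45) + 0.10 * g(720, 18) + 0.12 * g(810, 30) -
    0.10 * g(670, 15) - 0.08 * g(970, 35)
}

#' Generate synthetic spectra for a reference table
#'
#' Each deterministic spectrum is the fixed [grape_background()] plus the
#' sum over `band_specs` of `coefficient * parameter_value *
#' Gaussian(center, width)` plus the polynomial baseline. Each scan then
#' receives a multiplicative gain drawn uniformly from
#' `scatter_gain_range`, an additive normal offset and white noise, and is
#' clipped to (0, 1]. Ground truth records, per parameter, the grid indices
#' within one width of each planted band centre. The spectra stream is
#' seeded with `config$seed + 1` (the reference stream uses `config$seed`),
#' so a dataset is fully reproducible from the config alone.
#'
#' @param references a [reference_table()]; one sample per row.
#' @param config a [sim_config()].
#' @return an object of class `synthetic_dataset`: a list with elements
#'   `spectra` ([spectra_set()]), `references`, `ground_truth` (named list
#'   of index vectors) and `config`.
#' @export
generate_spectra <- function(references, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(references) < 1L) stop("references must be nonempty")
  wl <- config_wavelengths(config)
  p <- length(wl)
  n <- nrow(references)
  bs <- config$band_specs
  uwl <- (wl - min(wl)) / (max(wl) - min(wl))
  baseline <- rep(0, p)
  for (j in seq_along(config$baseline_poly_coeffs))
    baseline <- baseline + config$baseline_poly_coeffs[j] * uwl^(j - 1)
  base_curve <- grape_background(wl) + baseline
  S <- matrix(base_curve, n, p, byrow = TRUE)
  for (k in seq_len(nrow(bs))) {
    gk <- exp(-(wl - bs$center[k])^2 / (2 * bs$width[k]^2))
    val <- references[[bs$parameter[k]]]
    S <- S + tcrossprod(bs$coefficient[k] * val, gk)
  }
  nrep <- config$n_replicates
  nr <- n * nrep
  rows <- rep(seq_len(n), each = nrep)
  scat <- with_seed(config$seed + 1L, {
    gain <- stats::runif(nr, config$scatter_gain_range[1L],
                         config$scatter_gain_range[2L])
    offset <- if (config$scatter_offset_sd > 0)
      stats::rnorm(nr, 0, config$scatter_offset_sd) else rep(0, nr)
    noise <- if (config$noise_sd > 0)
      matrix(stats::rnorm(nr * p, 0, config$noise_sd), nr, p)
    else matrix(0, nr, p)
    list(gain = gain, offset = offset, noise = noise)
  })
  R <- S[rows, , drop = FALSE] * scat$gain + scat$offset + scat$noise
  R <- pmin(pmax(R, .Machine$double.eps), 1)
  ids <- references$sample_id[rows]
  meta <- data.frame(storage_day = references$day[rows],
                     temperature = references$temperature[rows],
                     stringsAsFactors = FALSE)
  if (nrep > 1L) {
    meta$replicate_group <- ids
    ids <- paste0(ids, "_r", rep(seq_len(nrep), times = n))
  }
  spectra <- spectra_set(R, wl, sample_ids = ids, metadata = meta)
  gt <- lapply(split(bs, bs$parameter), function(b) {
    sort(unique(unlist(lapply(seq_len(nrow(b)), function(k)
      which(abs(wl - b$center[k]) <= b$width[k])))))
  })
  structure(list(spectra = spectra, references = references,
                 ground_truth = gt, config = config),
            class = "synthetic_dataset")
}

#' @rdname generate_spectra
#' @export
generate_dataset <- function(config = sim_config()) {
  generate_spectra(generate_references(config), config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples, %d wavelengths, seed %d\n",
              nrow(x$references), n_wavelengths(x$spectra), x$config$seed))
  cat("  planted bands:",
      paste(sprintf("%s@%gnm", x$config$band_specs$parameter,
                    x$config$band_specs$center), collapse = ", "), "\n")
  invisible(x)
}
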