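# --- SPA ---------------------------------------------------------------

test_that("SPA chains follow projected-norm order on orthogonal columns", {
  # mutually orthogonal columns with norms 3 > 2 > 1: projection removes
  # nothing, so the chain is descending-norm order
  X <- cbind(c(3, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 1, 0))
  expect_equal(vinispec:::spa_chain(X, start = 1, max_vars = 3),
               c(1L, 2L, 3L))
  # starting elsewhere, the remaining columns still rank by norm
  expect_equal(vinispec:::spa_chain(X, start = 3, max_vars = 3),
               c(3L, 1L, 2L))
})

test_that("SPA never selects a duplicate of an already-chosen column", {
  set.seed(20)
  X <- matrix(rnorm(24), 6, 4)
  X <- cbind(X, X[, 1])  # column 5 duplicates column 1
  chain <- vinispec:::spa_chain(X, start = 1, max_vars = 5)
  expect_false(5L %in% chain)
})

test_that("SPA agrees with the Gram-Schmidt deflation oracle", {
  set.seed(21)
  for (rep in 1:20) {
    X <- matrix(rnorm(30), 6, 5)
    for (s0 in 1:5)
      expect_equal(vinispec:::spa_chain(X, s0, 4),
                   spa_oracle_chain(X, s0, 4))
  }
})

test_that("spa_select finds the informative variable and validates input", {
  set.seed(22)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- 3 * X[, 5] + rnorm(40, sd = 0.05)
  sr <- spa_select(X, y, max_vars = 4)
  expect_s3_class(sr, "selection_result")
  expect_true(5L %in% sr$selected_indices)
  expect_false(is.unsorted(sr$selected_indices))
  expect_length(sr$diagnostics$rmse_by_size,
                length(sr$diagnostics$chain))
  expect_error(spa_select(X, y, max_vars = 40), "max_vars")
  expect_error(spa_select(X, rep(1, 40), max_vars = 3), "zero variance")
})

# --- UVE ---------------------------------------------------------------

test_that("UVE keeps planted signal and drops noise variables", {
  n <- 30; p <- 20
  kept_signal <- 0L; noise_kept <- 0L; noise_total <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(n * p), n, p)
    y <- 5 * X[, 1] + rnorm(n, sd = 0.2)
    sr <- uve_select(X, y, n_lv = 3, seed = s)
    kept_signal <- kept_signal + (1L %in% sr$selected_indices)
    noise_kept <- noise_kept + sum(sr$selected_indices != 1L)
    noise_total <- noise_total + (p - 1L)
  }
  expect_equal(kept_signal, 20L)            # signal always survives
  expect_lt(noise_kept / noise_total, 0.10) # >= 90% of noise removed
})

test_that("UVE under the null retains few variables", {
  n <- 25; p <- 20
  kept <- 0L
  for (s in 1:20) {
    set.seed(200 + s)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    sr <- uve_select(X, y, n_lv = 3, threshold_factor = 1.0, seed = s)
    kept <- kept + length(sr$selected_indices)
  }
  expect_lt(kept / (20 * p), 0.10)
})

test_that("UVE threshold boundaries retain everything or nothing", {
  set.seed(30)
  X <- matrix(rnorm(200), 20, 10)
  y <- X[, 2] + rnorm(20, sd = 0.1)
  all_in <- uve_select(X, y, n_lv = 2, threshold_factor = 0, seed = 1)
  expect_equal(all_in$selected_indices, 1:10)
  none <- uve_select(X, y, n_lv = 2, threshold_factor = Inf, seed = 1)
  expect_length(none$selected_indices, 0L)
  expect_identical(uve_select(X, y, n_lv = 2, seed = 5)$selected_indices,
                   uve_select(X, y, n_lv = 2, seed = 5)$selected_indices)
  expect_error(uve_select(X[1:4, ], y[1:4], seed = 1), "at least 5")
  expect_error(uve_select(X, y), "seed")
})

# --- CARS --------------------------------------------------------------

test_that("CARS retention schedule hits its closed-form endpoints", {
  sch <- cars_schedule(p = 1401, n_runs = 100)
  expect_equal(sch$ratio[1], 1, tolerance = 1e-12)
  expect_equal(sch$ratio[100], 2 / 1401, tolerance = 1e-12)
  expect_equal(sch$k, log(1401 / 2) / 99)
  expect_equal(sch$a, exp(sch$k))
})

test_that("CARS traces are structurally consistent", {
  set.seed(40)
  X <- matrix(rnorm(40 * 60), 40, 60)
  y <- X[, 10] - 2 * X[, 40] + rnorm(40, sd = 0.2)
  sr <- cars_select(X, y, n_runs = 30, n_lv = 5, seed = 3)
  d <- sr$diagnostics
  expect_length(d$rmsecv, 30L)
  expect_length(d$n_retained, 30L)
  expect_true(all(diff(d$n_retained) <= 0))      # non-increasing
  expect_gte(min(d$n_retained), 2L)
  expect_equal(sr$best_run, which.min(d$rmsecv))
  expect_equal(sr$selected_indices, d$retained_sets[[sr$best_run]])
  expect_true(all(sr$selected_indices %in% 1:60))
  # reproducible given the seed, different otherwise
  sr2 <- cars_select(X, y, n_runs = 30, n_lv = 5, seed = 3)
  expect_identical(sr$selected_indices, sr2$selected_indices)
  expect_identical(sr$diagnostics$rmsecv, sr2$diagnostics$rmsecv)
  expect_error(cars_select(X[, 1:2], y, seed = 1), "at least 3")
  expect_error(cars_select(X, y), "seed")
})

test_that("CARS recovers planted absorption bands on coarse synthetic data", {
  hits <- 0L
  for (s in 1:5) {
    ds <- generate_dataset(coarse_config(seed = 300 + s))
    sp <- gradient_split(ds$references$SSC)
    cal <- subset_samples(ds$spectra, sp$calibration)
    Xc <- snv(cal)$reflectance
    sr <- cars_select(Xc, ds$references$SSC[sp$calibration],
                      n_runs = 50, seed = s)
    bands <- subset(ds$config$band_specs, parameter == "SSC")
    wl <- ds$spectra$wavelengths
    hit_all <- all(vapply(seq_len(nrow(bands)), function(k)
      any(abs(wl[sr$selected_indices] - bands$center[k]) <=
            bands$width[k]), logical(1)))
    hits <- hits + hit_all
  }
  expect_gte(hits, 4L)
})

test_that("selection results serialize to JSON", {
  set.seed(50)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- X[, 3] + rnorm(25, sd = 0.1)
  sr <- spa_select(X, y, max_vars = 3,
                   wavelengths = seq(400, 850, by = 50))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$method, "spa")
  expect_equal(back$selected_indices, sr$selected_indices)
  expect_equal(back$selected_nm, sr$selected_nm)
})
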