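test_that("metrics match their definitions", {
  y <- c(1, 2, 4, 7)
  perfect <- compute_metrics(y, y)
  expect_equal(perfect$R, 1)
  expect_equal(perfect$RMSE, 0)
  expect_equal(compute_metrics(c(0, 3), c(0, 4))$RMSE, sqrt(0.5))
  expect_equal(compute_metrics(y, -y)$R, -1)
  expect_equal(compute_metrics(y, 2 * y + 1)$R2, 1)
  expect_error(compute_metrics(rep(1, 4), y), "constant")
  expect_error(compute_metrics(y, y[1:3]), "length")
})

test_that("RPD is the prediction-set sd over RMSEP", {
  y <- c(0, 2.23 * sqrt(2))           # two-point set with sd = 2.23
  expect_equal(sd(y), 2.23, tolerance = 1e-12)
  expect_equal(compute_rpd(y, 0.984), 2.23 / 0.984, tolerance = 1e-12)
  expect_equal(compute_rpd(c(1, 2, 3), sd(c(1, 2, 3))), 1)
  expect_equal(compute_rpd(c(0, 1.5 * sqrt(2)), 0.5), 3)
  expect_warning(r0 <- compute_rpd(c(1, 2), 0), "infinite")
  expect_equal(r0, Inf)
})

test_that("pipelines never see prediction rows during fitting", {
  ds <- generate_dataset(coarse_config(n_samples = 40, seed = 77))
  y <- ds$references$SSC
  sp <- gradient_split(y)
  with_pred <- fit_pipeline(ds$spectra, y, sp$calibration, chain = "msc",
                            selector = "cars", model = "plsr",
                            selector_args = list(n_runs = 20), seed = 5)
  cal_only <- subset_samples(ds$spectra, sp$calibration)
  without_pred <- fit_pipeline(cal_only, y[sp$calibration],
                               seq_along(sp$calibration), chain = "msc",
                               selector = "cars", model = "plsr",
                               selector_args = list(n_runs = 20), seed = 5)
  expect_identical(with_pred$selected_indices,
                   without_pred$selected_indices)
  expect_identical(with_pred$model$coefficients,
                   without_pred$model$coefficients)
  pred_s <- subset_samples(ds$spectra, sp$prediction)
  expect_equal(predict(with_pred, pred_s), predict(without_pred, pred_s),
               tolerance = 1e-12)
})

test_that("pipeline predictions are frozen and grid-checked", {
  ds <- generate_dataset(coarse_config(n_samples = 30, seed = 78))
  y <- ds$references$TA
  sp <- gradient_split(y)
  pipe <- fit_pipeline(ds$spectra, y, sp$calibration, chain = "snv",
                       selector = "full", model = "plsr", seed = 1)
  cal_s <- subset_samples(ds$spectra, sp$calibration)
  expect_equal(unname(predict(pipe, cal_s)), pipe$model$fitted,
               tolerance = 1e-10)
  expect_error(predict(pipe, truncate_range(ds$spectra, 500, 900)),
               "grid mismatch")
})

test_that("the evaluation grid has the canonical shapes and is reproducible", {
  ds <- generate_dataset(coarse_config(seed = 80))
  t2 <- run_grid(ds, selectors = "full", models = "plsr", seed = 1)
  expect_s3_class(t2, "evaluation_report")
  expect_equal(nrow(t2), 18L)  # 3 parameters x 6 pretreatments
  expect_equal(sum(t2$best), 3L)

  fast <- list(spa = list(max_vars = 10), cars = list(n_runs = 25),
               uve = list(n_lv = 5))
  t3 <- run_grid(ds, chains = "snv", selectors = c("spa", "uve", "cars"),
                 models = c("plsr", "svm", "elm"), seed = 2,
                 selector_args = fast,
                 model_args = list(svm = list(c_grid = 2^(-2:4),
                                              g_grid = 2^(-6:0))))
  expect_equal(nrow(t3), 27L)  # 3 parameters x 3 selectors x 3 models
  # one wavelength subset per (parameter, selector), shared across models
  counts <- tapply(t3$n_selected,
                   interaction(t3$parameter, t3$selector),
                   function(v) length(unique(v)))
  expect_true(all(counts == 1L))
  t3b <- run_grid(ds, chains = "snv", selectors = c("spa", "uve", "cars"),
                  models = c("plsr", "svm", "elm"), seed = 2,
                  selector_args = fast,
                  model_args = list(svm = list(c_grid = 2^(-2:4),
                                               g_grid = 2^(-6:0))))
  expect_identical(t3, t3b)

  # consistency identity: RPD * RMSEP == sd(prediction-set reference)
  refs <- ds$references
  for (i in seq_len(nrow(t2))) {
    pm <- t2$parameter[i]
    sp <- gradient_split(refs[[pm]])
    expect_equal(t2$RPD[i] * t2$RMSEP[i], sd(refs[[pm]][sp$prediction]),
                 tolerance = 1e-10)
  }
})

test_that("weak-band parameter scores below strong-band parameters", {
  ds <- generate_dataset(coarse_config(seed = 81))
  rep <- run_grid(ds, chains = "snv", selectors = "cars",
                  models = "plsr", seed = 3,
                  selector_args = list(cars = list(n_runs = 40)))
  best <- tapply(rep$RPD, rep$parameter, max)
  expect_lt(best["pH"], best["SSC"])
  expect_lt(best["pH"], best["TA"])
})

test_that("reports serialize to CSV and JSON", {
  ds <- generate_dataset(coarse_config(n_samples = 24, seed = 82))
  rep <- run_grid(ds, parameters = "SSC", chains = c("raw", "snv"),
                  seed = 4)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report_csv(rep, csv)
  write_report_json(rep, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 2L)
  expect_equal(back$RPD, rep$RPD, tolerance = 1e-10)
  jb <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(jb$RMSEP, rep$RMSEP, tolerance = 1e-12)
})
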