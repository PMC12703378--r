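test_that("first derivative matches hand-computed finite differences", {
  wl <- seq(400, 500, by = 10)
  const <- tiny_spectra(matrix(3, 1, 11), wl)
  expect_true(all(first_derivative(const)$reflectance == 0))

  lin <- tiny_spectra(matrix(2 * wl, 1, 11, byrow = TRUE), wl)
  d <- first_derivative(lin)$reflectance[1, ]
  expect_equal(d[2:10], rep(2, 9), ignore_attr = TRUE)
  expect_equal(d[c(1, 11)], c(2, 2), ignore_attr = TRUE)  # one-sided ends

  # non-uniform grid: central difference of x^2 on {1,2,4} at 2 is
  # (16 - 1) / (4 - 1) = 5
  sq <- tiny_spectra(matrix(c(1, 4, 16), 1), wl = c(1, 2, 4))
  expect_equal(first_derivative(sq)$reflectance[1, 2], 5,
               ignore_attr = TRUE)

  expect_error(first_derivative(tiny_spectra(matrix(1, 1, 2))),
               "at least 3")
})

test_that("Savitzky-Golay reproduces low-order polynomials exactly", {
  wl <- seq_len(31)
  spec <- tiny_spectra(matrix(2 + 0.5 * wl - 0.03 * wl^2, 1, byrow = TRUE),
                       wl)
  sm <- savitzky_golay(spec, window = 7, polyorder = 2)
  expect_equal(sm$reflectance, spec$reflectance, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(savitzky_golay(spec, window = 6), "odd")
  expect_error(savitzky_golay(spec, window = 3, polyorder = 3),
               "exceed polyorder")
  expect_error(savitzky_golay(spec, window = 33), "number of wavelengths")
})

test_that("SG impulse response is the classic quadratic kernel", {
  x <- rep(0, 11); x[6] <- 1
  sm <- savitzky_golay(tiny_spectra(matrix(x, 1, byrow = TRUE)),
                       window = 5, polyorder = 2)
  expect_equal(sm$reflectance[1, 4:8], c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("SG smoothing reduces white-noise variance", {
  set.seed(1)
  noisy <- tiny_spectra(matrix(rnorm(500), 2, 250))
  sm <- savitzky_golay(noisy, window = 11, polyorder = 2)
  expect_lt(var(sm$reflectance[1, ]), var(noisy$reflectance[1, ]))
  expect_lt(var(sm$reflectance[2, ]), var(noisy$reflectance[2, ]))
})

test_that("SNV centres and scales each spectrum", {
  s <- tiny_spectra(matrix(c(1, 2, 3), 1, byrow = TRUE))
  expect_equal(snv(s)$reflectance[1, ], c(-1, 0, 1), ignore_attr = TRUE)

  set.seed(2)
  X <- matrix(runif(60), 4, 15)
  out <- snv(tiny_spectra(X))$reflectance
  expect_equal(unname(rowMeans(out)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(out, 1, sd)), rep(1, 4), tolerance = 1e-10)

  # affine invariance: snv(a*x + b) == snv(x) for a > 0
  aff <- snv(tiny_spectra(2.5 * X + 7))$reflectance
  expect_equal(aff, out, tolerance = 1e-10)

  expect_error(snv(tiny_spectra(matrix(5, 2, 4))), "zero-variance")
})

test_that("MSC corrects pure gain/offset distortion exactly", {
  set.seed(3)
  ref <- runif(20)

  # x equal to the reference comes back unchanged
  same <- msc_fit_apply(tiny_spectra(rbind(ref, ref)))
  expect_equal(same$reflectance[1, ], ref, tolerance = 1e-10,
               ignore_attr = TRUE)

  # x = 2*ref + 5 is restored to ref exactly
  dist <- msc_fit_apply(ref, tiny_spectra(matrix(2 * ref + 5, 1,
                                                 byrow = TRUE)))
  expect_equal(dist$reflectance[1, ], ref, tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(msc_fit_apply(tiny_spectra(matrix(1, 3, 5))), "constant")
})

test_that("SNV and MSC collapse gain/offset scatter on synthetic spectra", {
  rr <- default_reference_ranges()
  rr$sd <- 0  # identical reference values: spectra differ only by scatter
  ds <- generate_dataset(clean_config(scatter_gain_range = c(0.8, 1.2),
                                      scatter_offset_sd = 0.05,
                                      reference_ranges = rr,
                                      n_samples = 12))
  raw <- ds$spectra$reflectance
  expect_gt(max(dist(raw)), 0.1)  # scatter clearly separates raw scans
  for (corrected in list(snv(ds$spectra)$reflectance,
                         msc_fit_apply(ds$spectra)$reflectance)) {
    d <- as.matrix(dist(corrected))
    expect_lt(max(d), 1e-8)
  }
})

test_that("chains compose left-to-right and freeze MSC on calibration", {
  ds <- generate_dataset(coarse_config(n_samples = 20))
  s <- ds$spectra
  fitted <- fit_preprocess(preprocess_chain("fd+sg"), s)
  combo <- apply_preprocess(fitted, s)
  manual <- savitzky_golay(first_derivative(s))
  expect_spectra_equal(combo, manual)
  # order matters
  swapped <- first_derivative(savitzky_golay(s))
  expect_gt(max(abs(swapped$reflectance - combo$reflectance)), 1e-8)

  # the raw chain is the identity
  expect_spectra_equal(
    apply_preprocess(fit_preprocess(preprocess_chain("raw"), s), s), s)

  # MSC reference comes from the calibration set only
  cal <- subset_samples(s, 1:12)
  new <- subset_samples(s, 13:20)
  f <- fit_preprocess(preprocess_chain("msc"), cal)
  got <- apply_preprocess(f, new)
  frozen <- msc_fit_apply(colMeans(cal$reflectance), new)
  expect_spectra_equal(got, frozen)

  expect_error(preprocess_chain("emsc"), "unknown preprocessing step")
  expect_error(apply_preprocess(f, truncate_range(s, 500, 900)), "grid")
})
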