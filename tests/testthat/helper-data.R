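# fixtures built in code ------------------------------------------------

# coarse grid (5 nm step, 141 points) keeps unit tests fast; band centres
# of the default band_specs all lie on this grid too
coarse_config <- function(...) {
  args <- list(...)
  defaults <- list(wavelength_step_nm = 5, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# scatter-free, noise-free config: spectra are exact linear functions of
# the reference values
clean_config <- function(...) {
  args <- list(...)
  defaults <- list(noise_sd = 0, scatter_gain_range = c(1, 1),
                   scatter_offset_sd = 0)
  do.call(coarse_config, utils::modifyList(defaults, args))
}

tiny_spectra <- function(mat, wl = seq_len(ncol(mat))) {
  mat <- as.matrix(mat)
  rownames(mat) <- NULL
  spectra_set(mat, wl)
}

# independent SPA oracle: explicit Gram-Schmidt deflation of the full
# matrix (the implementation instead updates squared norms against an
# orthonormal basis; the two must agree)
spa_oracle_chain <- function(X, start, max_vars) {
  X <- as.matrix(X)
  tol <- 1e-12 * max(colSums(X^2))
  chain <- start
  Xp <- X
  while (length(chain) < max_vars) {
    v <- Xp[, chain[length(chain)]]
    Xp <- Xp - v %*% crossprod(v, Xp) / sum(v^2)
    norms2 <- colSums(Xp^2)
    norms2[chain] <- -1
    nxt <- which.max(norms2)
    if (norms2[nxt] <= tol) break
    chain <- c(chain, nxt)
  }
  chain
}

expect_spectra_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$wavelengths, b$wavelengths, tolerance = tol)
  expect_equal(a$reflectance, b$reflectance, tolerance = tol,
               ignore_attr = TRUE)
}
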