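test_that("spike-triggered average is the count-weighted stimulus mean", {
  X <- matrix(rnorm(50 * 6), 50, 6)
  r <- integer(50); r[17] <- 1L
  expect_equal(compute_sta(X, r), X[17, ])
  r2 <- c(2L, 1L, integer(48))
  expect_equal(compute_sta(X, r2), (2 * X[1, ] + X[2, ]) / 3)
  expect_error(compute_sta(X, integer(50)), "no spikes")
})

test_that("STA of stimulus-independent counts is statistically null", {
  fx <- small_cell(seed = 10, n_pulses = 20000)
  r <- as.numeric(fx$resp)
  r_shuf <- circshift_counts(r, 4321)
  sta <- compute_sta(fx$design, r_shuf)
  # CLT bound: per-entry SE of the weighted mean
  sig <- sd(unclass(fx$design))
  se <- sig * sqrt(sum(r_shuf^2)) / sum(r_shuf)
  expect_true(all(abs(sta) < 4.5 * se))
})

test_that("a symmetric pure-quadratic cell leaves the STA near zero", {
  fx <- small_cell(seed = 11, n_pulses = 20000, n_exc = 1, n_sup = 0,
                   v0_sd = 0)
  sta <- compute_sta(fx$design, fx$resp)
  r <- as.numeric(fx$resp)
  sig <- sd(unclass(fx$design))
  se <- sig * sqrt(sum(r^2)) / sum(r)
  # norm comparable to the null expectation (d * se^2), far from signal
  expect_lt(sum(sta^2), 3 * ncol(fx$design) * se^2)
})

test_that("STC eigenvectors recover planted components", {
  fx <- small_cell(seed = 12, n_pulses = 25000)
  stc <- compute_stc(fx$design, fx$resp)
  d <- ncol(fx$design)
  expect_gt(abs_cosine(stc$eigenvectors[, 1], fx$gt$directions[, 1]), 0.9)
  expect_gt(abs_cosine(stc$eigenvectors[, d], fx$gt$directions[, 2]), 0.9)
  # orthonormal eigenvectors, conserved trace
  gram <- crossprod(stc$eigenvectors)
  expect_lt(max(abs(gram - diag(d))), 1e-9)
  r <- as.numeric(fx$resp)
  X <- unclass(fx$design); attributes(X) <- list(dim = dim(fx$design))
  Xc <- sweep(X, 2, stc$sta)
  tr_C <- sum(colSums(Xc^2 * r) / sum(r))
  expect_equal(sum(stc$eigenvalues), tr_C, tolerance = 1e-9)
  # deterministic sign convention
  for (j in c(1, d)) {
    expect_gt(stc$eigenvectors[which.max(abs(stc$eigenvectors[, j])), j], 0)
  }
})

test_that("shuffle null bounds are quantiles, reproducible and honoured", {
  fx <- small_cell(seed = 13, n_pulses = 6000, n_electrodes = 6)
  ci <- eigenvalue_null_ci(fx$design, fx$resp, n_shuffles = 150,
                           alpha = 0.05, seed = 2)
  ci2 <- eigenvalue_null_ci(fx$design, fx$resp, n_shuffles = 150,
                            alpha = 0.05, seed = 2)
  expect_identical(ci, ci2)
  expect_true(all(ci$null_lo <= ci$null_hi))
  tiny <- build_design_matrix(
    sample_white_noise_train(7, 3, frequency_hz = 10, seed = 1))
  expect_error(eigenvalue_null_ci(tiny, rep(1L, nrow(tiny)),
                                  n_shuffles = 150),
               "too short")
  expect_error(eigenvalue_null_ci(fx$design, fx$resp, n_shuffles = 10),
               "n_shuffles")

  stc <- compute_stc(fx$design, fx$resp, null_ci = ci)
  expect_true(all(stc$eigenvalues[stc$significant_exc] >
                    ci$null_hi[stc$significant_exc]))
  expect_true(all(stc$eigenvalues[stc$significant_sup] <
                    ci$null_lo[stc$significant_sup]))
})

test_that("planted excitatory and suppressive ranks are detected", {
  fx <- small_cell(seed = 14, n_pulses = 25000, n_electrodes = 8,
                   n_exc = 2, n_sup = 2)
  stc <- stc_analysis(fx$design, fx$resp, n_shuffles = 200, seed = 3)
  d <- ncol(fx$design)
  expect_true(all(c(1, 2) %in% stc$significant_exc))
  expect_true(all(c(d - 1, d) %in% stc$significant_sup))
  # the planted subspace is spanned by the extreme eigenvectors
  for (i in 1:2) {
    expect_gt(abs_cosine(stc$eigenvectors[, i], fx$gt$directions[, i]), 0.85)
  }
})
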