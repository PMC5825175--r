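# Minimal fitted-model scaffold with a chosen significance mask.
masked_model <- function(L, ne, w, mask_entries, frequency_hz) {
  d <- L * ne
  V <- matrix(0.1, d, length(w))
  mask <- matrix(FALSE, d, length(w))
  for (e in mask_entries) mask[e$idx, e$comp] <- TRUE
  new_gqm(numeric(d), V, w, c(a = 3, b = 2, c = 1), L = L,
          n_electrodes = ne, frequency_hz = frequency_hz,
          sig_mask = list(v0 = rep(FALSE, d), components = mask))
}

test_that("integration time is the latest significant lag per class", {
  # excitatory entries only at lag 0
  m <- masked_model(6, 4, c(1, -1),
                    list(list(idx = 2, comp = 1), # lag 0
                         list(idx = 4 + 1, comp = 2)), # lag 1
                    frequency_hz = 20)
  it <- integration_time(m)
  expect_equal(it$integration_ms, c(0, 50))
  expect_true(all(it$any_significant))

  m30 <- masked_model(9, 4, c(1),
                      list(list(idx = c(1, 5, 9), comp = 1)), # lags 0,1,2
                      frequency_hz = 30)
  expect_equal(integration_time(m30)$integration_ms[1], 2000 / 30)

  # empty mask reported as 0 and flagged
  m0 <- masked_model(3, 4, c(1), list(), frequency_hz = 10)
  it0 <- integration_time(m0)
  expect_equal(it0$integration_ms, c(0, 0))
  expect_false(any(it0$any_significant))
  # integration times are multiples of the inter-pulse interval
  expect_equal(it$integration_ms %% 50, c(0, 0))
})

test_that("ERF size is the amplitude-weighted distance to the recording site", {
  arr <- manual_array(x_mm = c(0, 1, 2), y_mm = c(0, 0, 0))
  # single significant electrode at the recording location
  comp <- c(5, 0, 0)
  expect_equal(erf_size(comp, c(TRUE, FALSE, FALSE), arr), 0)
  # two equal amplitudes at 1 and 2 mm
  expect_equal(erf_size(c(0, 1, 1), c(FALSE, TRUE, TRUE), arr), 1.5)
  # amplitudes 3 and 1 at 1 and 2 mm
  expect_equal(erf_size(c(0, 3, 1), c(FALSE, TRUE, TRUE), arr), 1.25)
  # invariant to rescaling the component
  expect_equal(erf_size(c(0, 30, 10), c(FALSE, TRUE, TRUE), arr), 1.25)
  # multiple lags: weights accumulate per (lag, electrode) entry
  expect_equal(erf_size(c(0, 1, 0, 0, 0, 1), rep(c(FALSE, TRUE, FALSE,
                                                   FALSE, FALSE, TRUE), 1),
                        arr), 1.5)
  expect_warning(out <- erf_size(comp, rep(FALSE, 3), arr), "undefined")
  expect_true(is.na(out))
})

test_that("polarity preference is symmetric for a pure quadratic cell", {
  fx <- small_cell(seed = 31, n_pulses = 30000, n_exc = 1, n_sup = 0,
                   v0_sd = 0)
  pol <- polarity_preference(fx$gt$directions[, 1], fx$design, fx$resp)
  expect_true(pol$applicable)
  expect_equal(max(pol$anodic_sat, pol$cathodic_sat), 1)
  expect_gt(min(pol$anodic_sat, pol$cathodic_sat), 0.7)
})

test_that("a linear filter along the component skews the polarity", {
  fx <- small_cell(seed = 32, n_pulses = 30000, n_exc = 1, n_sup = 0,
                   mode = "direct", v0_sd = 0.5)
  # v0 is aligned with +direction: positive projections drive more spikes
  pol <- polarity_preference(fx$gt$directions[, 1], fx$design, fx$resp)
  expect_equal(pol$anodic_sat, 1)
  expect_lt(pol$cathodic_sat, 0.9)
  # mixed-polarity significant electrodes are flagged non-applicable
  comp <- fx$gt$directions[, 1]
  mask <- abs(comp) > 0.3
  comp_mixed <- comp; comp_mixed[which(mask)[1]] <- -comp[which(mask)[1]]
  polm <- polarity_preference(comp_mixed, fx$design, fx$resp,
                              sig_mask = mask)
  expect_false(polm$applicable)
})

test_that("linear-filter reconstruction from the quadratic subspace", {
  set.seed(33)
  V <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  # v0 inside the span: similarity 1
  v_in <- V %*% c(1, -2, 0.5)
  expect_equal(linear_component_similarity(v_in, V)$similarity, 1,
               tolerance = 1e-12)
  # v0 orthogonal to the span: similarity 0
  v_out <- rnorm(40)
  v_out <- v_out - V %*% crossprod(V, v_out)
  expect_equal(linear_component_similarity(v_out, V)$similarity, 0,
               tolerance = 1e-12)
  # zero filter flagged
  expect_warning(res <- linear_component_similarity(numeric(40), V),
                 "undefined")
  expect_true(is.na(res$similarity))
  # invariance to orthonormal re-basing of the subspace
  v0 <- rnorm(40)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  s1 <- linear_component_similarity(v0, V)$similarity
  s2 <- linear_component_similarity(v0, V %*% Q)$similarity
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_error(linear_component_similarity(v0, cbind(V[, 1], V[, 1])),
               "not orthogonal")
})

test_that("a weighted component sum reconstructs the linear filter", {
  # a cell whose v0 lies mostly in the quadratic subspace, with the
  # orthogonal remainder sized for cosine similarity 0.88
  set.seed(34)
  V <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
  b <- c(0.97, -0.19, -0.14)
  u0 <- as.numeric(V %*% b)
  rem <- rnorm(60)
  rem <- rem - as.numeric(V %*% crossprod(V, rem))
  rem <- rem / sqrt(sum(rem^2))
  target <- sqrt(sum(u0^2)) / 0.88
  v0 <- u0 + rem * sqrt(target^2 - sum(u0^2))
  res <- linear_component_similarity(v0, V)
  expect_equal(res$similarity, 0.88, tolerance = 1e-6)
  expect_equal(res$b_weights, b, tolerance = 1e-9)
  expect_equal(res$u0, u0, tolerance = 1e-9)
})

test_that("erf_summary assembles the per-cell characterization", {
  fx <- small_cell(seed = 35, n_pulses = 10000, n_electrodes = 8)
  m <- fit_gqm(fx$design, fx$resp, 1, 1, seed = 1)
  m <- electrode_significance(m, fx$design, fx$resp, n_boot = 100, seed = 2)
  arr <- make_electrode_array(8)
  sm <- erf_summary(m, arr, fx$design, fx$resp)
  expect_s3_class(sm$components, "tbl_df")
  expect_equal(nrow(sm$components), 2)
  expect_equal(sm$integration$class, c("excitatory", "suppressive"))
  expect_true(all(is.na(sm$components$erf_size_mm) |
                    sm$components$erf_size_mm >= 0))
  expect_true(is.na(sm$similarity) ||
                (sm$similarity >= 0 && sm$similarity <= 1))
})
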