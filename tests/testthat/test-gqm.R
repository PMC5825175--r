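# Scalar-loop reference implementations used as independent oracles.
ref_generator <- function(v0, comps, w, S) {
  out <- numeric(nrow(S))
  for (t in seq_len(nrow(S))) {
    g <- 0
    for (j in seq_along(v0)) g <- g + v0[j] * S[t, j]
    for (i in seq_along(w)) {
      p <- 0
      for (j in seq_along(v0)) p <- p + comps[[i]][j] * S[t, j]
      g <- g + w[i] * p * p
    }
    out[t] <- g
  }
  out
}

ref_poisson_ll <- function(rates, counts) {
  total <- 0
  for (t in seq_along(rates)) {
    term <- -rates[t]
    if (counts[t] > 0) term <- term + counts[t] * log(rates[t])
    total <- total + term
  }
  total
}

test_that("generator signal matches a scalar-loop reference", {
  set.seed(21)
  for (rep in 1:20) {
    d <- sample(3:8, 1); N <- sample(0:3, 1)
    v0 <- rnorm(d)
    V <- matrix(rnorm(d * N), d, N)
    w <- sample(c(-1, 1), N, replace = TRUE)
    m <- new_gqm(v0, V, w, sigmoid = c(a = 3, b = 2, c = 1))
    S <- matrix(rnorm(10 * d), 10, d)
    expect_equal(generator_signal(m, S),
                 ref_generator(v0, asplit(V, 2), w, S), tolerance = 1e-12)
  }
  # unit component against itself
  v <- c(1, 0, 0)
  m_exc <- new_gqm(numeric(3), matrix(v), 1, c(a = 3, b = 2, c = 1))
  m_sup <- new_gqm(numeric(3), matrix(v), -1, c(a = 3, b = 2, c = 1))
  expect_equal(generator_signal(m_exc, v), 1)
  expect_equal(generator_signal(m_sup, v), -1)
  expect_error(generator_signal(m_exc, c(1, 2)), "mismatch")
})

test_that("expected response is the sigmoid of the generator", {
  m <- new_gqm(c(1, 0), matrix(0, 2, 0), numeric(0),
               sigmoid = c(a = 3, b = 2, c = 1))
  expect_equal(expected_response(m, c(1, 0)), 1.5) # g = c gives a/2
  expect_equal(expected_response(m, c(100, 0)), 3, tolerance = 1e-9)
  expect_equal(expected_response(m, c(-100, 0)), 0, tolerance = 1e-9)
})

test_that("Poisson log-likelihood matches a term-by-term reference", {
  expect_equal(poisson_log_likelihood(1, 1), -1)
  expect_equal(poisson_log_likelihood(2, 0), -2)
  expect_identical(poisson_log_likelihood(c(0, 1), c(1, 0)), -Inf)
  expect_error(poisson_log_likelihood(c(-1, 1), c(0, 0)), "negative")
  set.seed(22)
  for (rep in 1:20) {
    rates <- rexp(100, 1)
    counts <- rpois(100, rates)
    expect_equal(poisson_log_likelihood(rates, counts),
                 ref_poisson_ll(rates, counts), tolerance = 1e-12)
  }
})

test_that("canonicalization preserves the generator and merges parallels", {
  set.seed(23)
  d <- 15
  V <- matrix(rnorm(d * 3), d, 3)
  m <- new_gqm(rnorm(d), V, c(1, 1, -1), c(a = 3, b = 2, c = 1))
  mc <- canonicalize_components(m)
  S <- matrix(rnorm(1000 * d), 1000, d)
  expect_lt(max(abs(generator_signal(m, S) - generator_signal(mc, S))),
            1e-10)
  # canonical components are orthogonal with norm sqrt(|eigenvalue|)
  gram <- crossprod(mc$V)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-9)

  # already-orthogonal components come back unchanged up to sign
  Q <- qr.Q(qr(matrix(rnorm(d * 2), d, 2))) %*% diag(c(2, 1))
  m2 <- new_gqm(numeric(d), Q, c(1, 1), c(a = 3, b = 2, c = 1))
  mc2 <- canonicalize_components(m2)
  for (i in 1:2) expect_gt(abs_cosine(mc2$V[, i], Q[, i]), 1 - 1e-9)

  # parallel components collapse to one with the combined strength
  v <- rnorm(d)
  m3 <- new_gqm(numeric(d), cbind(v, 2 * v), c(1, 1), c(a = 3, b = 2, c = 1))
  mc3 <- canonicalize_components(m3)
  expect_equal(ncol(mc3$V), 1)
  expect_equal(sum(mc3$V[, 1]^2), 5 * sum(v^2), tolerance = 1e-9)
})

test_that("sigmoid nonlinearity fit recovers known parameters", {
  set.seed(24)
  g <- rnorm(20000, 1, 1.2)
  counts <- rpois(20000, 3 / (1 + exp(-2 * (g - 1))))
  sf <- fit_sigmoid_nonlinearity(g, counts)
  expect_equal(sf$a, 3, tolerance = 0.1)
  expect_equal(sf$b, 2, tolerance = 0.2)
  expect_equal(sf$c, 1, tolerance = 0.1)
  expect_false(sf$flat)
  expect_equal(nrow(sf$binned_curve), 100)
  # bin means are exact arithmetic means (recompute bin 1 independently)
  ord <- order(g)
  expect_equal(sf$binned_curve$response_mean[1],
               mean(counts[ord[1:200]]))
  expect_equal(sf$binned_curve$g_mean[1], mean(g[ord[1:200]]))
  # flat data flagged, saturation equals the constant
  sff <- fit_sigmoid_nonlinearity(g, rep(2, 20000))
  expect_true(sff$flat)
  expect_equal(sff$a, 2)
  expect_error(fit_sigmoid_nonlinearity(g[1:300], counts[1:300]),
               "two complete bins")
})

test_that("likelihood ascends during fitting and from a truth warm start", {
  fx <- small_cell(seed = 25, n_pulses = 10000)
  m <- fit_gqm(fx$design, fx$resp, 1, 1, seed = 1)
  path <- m$fit_meta$loglik_path
  expect_true(all(diff(path) > -1e-6 * abs(path[-length(path)])))

  # initializing at the ground truth cannot lose likelihood
  gt_model <- new_gqm(
    v0 = fx$gt$v0,
    V = do.call(cbind, lapply(fx$gt$components, `[[`, "v")),
    w = fx$gt$w, sigmoid = fx$gt$sigmoid
  )
  ll0 <- gqm_log_likelihood(gt_model, fx$design, fx$resp)
  m2 <- fit_gqm(fx$design, fx$resp, 1, 1, warm_start = gt_model, seed = 1,
                canonicalize = FALSE)
  expect_gte(m2$fit_meta$loglik, ll0 - 1e-6 * abs(ll0))
})

test_that("a one-component cell is recovered from its spikes", {
  fx <- small_cell(seed = 26, n_pulses = 20000, n_exc = 1, n_sup = 0)
  m <- fit_gqm(fx$design, fx$resp, 1, 0, seed = 1)
  expect_gt(abs_cosine(m$V[, 1], fx$gt$directions[, 1]), 0.9)
  expect_equal(m$sigmoid[["a"]], fx$gt$sigmoid[["a"]], tolerance = 0.25)
  # the order-zero model reduces to a linear-filter LN fit
  m0 <- fit_gqm(fx$design, fx$resp, 0, 0, seed = 1)
  expect_equal(ncol(m0$V), 0)
})

test_that("response contours are the predicted conics", {
  fx <- small_cell(seed = 27, n_pulses = 15000)
  m <- fit_gqm(fx$design, fx$resp, 1, 1, seed = 1)
  ct <- response_contour(m, 1, 2, level = 1)
  expect_equal(unname(ct$coef[c("w_i", "w_j")]), c(1, -1)) # exc-sup pair
  # sampled contour points reproduce the requested rate through the model
  ui <- m$V[, 1] / sqrt(sum(m$V[, 1]^2)); ni <- sqrt(sum(m$V[, 1]^2))
  uj <- m$V[, 2] / sqrt(sum(m$V[, 2]^2)); nj <- sqrt(sum(m$V[, 2]^2))
  pts <- ct$points[round(seq(1, nrow(ct$points), length.out = 25)), ]
  S <- outer(pts$x / ni, ui) + outer(pts$y / nj, uj)
  expect_lt(max(abs(expected_response(m, S) - 1)), 1e-9)
  expect_error(response_contour(m, 1, 2, level = 10), "range")
  expect_error(response_contour(m, 1, 1, level = 1))
})

test_that("bootstrap significance flags planted electrodes", {
  fx <- small_cell(seed = 28, n_pulses = 10000, n_electrodes = 8)
  m <- fit_gqm(fx$design, fx$resp, 1, 1, seed = 1)
  expect_warning(
    electrode_significance(m, fx$design, fx$resp, n_boot = 30, seed = 1),
    "unstable"
  )
  m <- electrode_significance(m, fx$design, fx$resp, n_boot = 120, seed = 2)
  for (i in 1:2) {
    truth <- fx$gt$directions[, i]
    strong <- abs(truth) > 0.5 * max(abs(truth))
    expect_true(all(m$sig_mask$components[strong, i]))
    expect_lt(mean(m$sig_mask$components[!strong, i]), 0.25)
  }
  # tidy() exposes the mask alongside coefficients
  td <- tidy(m)
  expect_equal(nrow(td), (ncol(m$V) + 1) * length(m$v0))
  expect_true(any(td$significant))
})
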