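test_that("hexagonal array geometry matches the stimulation protocol", {
  arr <- make_electrode_array(20, pitch_mm = 1, diameter_um = 400)
  expect_equal(nrow(arr), 20)
  # footprint approximately 3.5 x 3.5 mm
  expect_equal(diff(range(arr$x_mm)), 3.5, tolerance = 0.05)
  expect_equal(diff(range(arr$y_mm)), 3.5, tolerance = 0.05)
  # nearest-neighbour distance equals the pitch for every electrode
  d <- as.matrix(stats::dist(cbind(arr$x_mm, arr$y_mm)))
  diag(d) <- Inf
  expect_true(all(abs(apply(d, 1, min) - 1) < 1e-9))
  expect_equal(nrow(dplyr::distinct(arr, x_mm, y_mm)), 20)

  # centred hexagon: middle electrode has six neighbours at one pitch
  arr7 <- make_electrode_array(7)
  d7 <- as.matrix(stats::dist(cbind(arr7$x_mm, arr7$y_mm)))
  expect_equal(sum(abs(d7[1, -1] - 1) < 1e-9), 6)

  solo <- make_electrode_array(1, recording_loc = c(0.5, -1))
  expect_equal(c(solo$x_mm, solo$y_mm), c(0.5, -1))

  expect_error(make_electrode_array(0), "n_electrodes")
  expect_error(make_electrode_array(5, pitch_mm = -1), "pitch_mm")
})

test_that("white-noise trains have truncated-Gaussian statistics", {
  tr <- sample_white_noise_train(25000, 8, seed = 7)
  x <- as.numeric(train_matrix(tr))
  expect_true(all(abs(x) <= 300))
  # empirical SD near the closed form (SE of SD ~ 0.15% here)
  expect_equal(sd(x), truncated_gaussian_sd(150, 300), tolerance = 0.01)
  # effectively untruncated when the limit is far out
  tr2 <- sample_white_noise_train(50000, 4, limit_ua = 1e6, seed = 8)
  expect_equal(sd(as.numeric(train_matrix(tr2))), 150, tolerance = 0.02)
  # determinism
  tr3 <- sample_white_noise_train(25000, 8, seed = 7)
  expect_identical(train_matrix(tr), train_matrix(tr3))
  expect_warning(sample_white_noise_train(10, 1, sigma_ua = 1000,
                                          limit_ua = 1, seed = 1),
                 "degenerate")
})

test_that("white-noise amplitudes pass a KS test against the truncated CDF", {
  tr <- sample_white_noise_train(100000, 1, seed = 42)
  ks <- suppressWarnings(stats::ks.test(
    as.numeric(train_matrix(tr)),
    function(q) truncated_gaussian_cdf(q, 150, 300)
  ))
  expect_gt(ks$p.value, 0.01)
})

test_that("design matrix lags, shape and ordering follow the 300 ms window", {
  for (f in c(10, 20, 30)) {
    tr <- sample_white_noise_train(100, 4, frequency_hz = f, seed = 1)
    X <- build_design_matrix(tr)
    expect_equal(attr(X, "L"), round(0.3 * f))
    expect_equal(nrow(X), 100 - round(0.3 * f) + 1)
    expect_equal(attr(X, "lag_times_ms")[2], -1000 / f)
  }
  tr <- sample_white_noise_train(100, 4, frequency_hz = 10, seed = 2)
  A <- train_matrix(tr)
  X <- build_design_matrix(tr)
  # lag-0 block of row t equals pulse row t + L - 1
  expect_equal(unname(X[5, 1:4]), A[7, ])
  # full round trip for every row
  for (t in c(1, 50, 98)) {
    h <- design_row_history(X, t)
    expect_equal(h, A[(t + 2):t, , drop = FALSE], ignore_attr = TRUE)
  }
  expect_error(build_design_matrix(tr, window_ms = 50), "inter-pulse")
  expect_equal(length(align_responses(seq_len(100), X)), nrow(X))
})

test_that("structured images follow the generation rules", {
  img <- render_structured_image("spots", seed = 1)
  expect_equal(dim(img), c(500, 500))
  expect_equal(max(abs(img)), 250)
  expect_identical(unclass(img),
                   unclass(render_structured_image("spots", seed = 1)))
  # scaling is idempotent
  expect_equal(unclass(img) * (250 / max(abs(img))), unclass(img))

  g <- render_structured_image("static_grating", seed = 3)
  expect_equal(max(abs(g)), 250)
  # dominant spatial frequency below the 0.5 cycles/mm Nyquist limit
  sp <- Mod(stats::fft(unclass(g)))^2
  sp[1, 1] <- 0
  pk <- which(sp == max(sp), arr.ind = TRUE)[1, ]
  cyc_px <- sqrt(min(pk[1] - 1, 500 - pk[1] + 1)^2 +
                   min(pk[2] - 1, 500 - pk[2] + 1)^2) / 500
  expect_lt(cyc_px * 100, 0.5) # 100 px per mm

  mv <- render_structured_image("moving_grating", seed = 4,
                                frequency_hz = 30)
  expect_length(mv, 9) # 300 ms at 30 Hz
  expect_equal(max(vapply(mv, function(f) max(abs(f)), numeric(1))), 250)
  mv10 <- render_structured_image("moving_grating", seed = 4,
                                  frequency_hz = 10)
  expect_length(mv10, 3)
})

test_that("electrode sampling reads the pixel at each electrode centre", {
  arr <- make_electrode_array(20)
  uni <- matrix(17, 500, 500)
  class(uni) <- c("stim_image", class(uni))
  attr(uni, "pixel_pitch_um") <- 10
  expect_equal(image_to_pulse_amplitudes(uni, arr), rep(17, 20))
  zero <- uni * 0
  class(zero) <- c("stim_image", class(zero))
  attr(zero, "pixel_pitch_um") <- 10
  expect_equal(image_to_pulse_amplitudes(zero, arr), rep(0, 20))

  # single bright pixel at one electrode centre
  ctr <- c(mean(arr$x_mm), mean(arr$y_mm))
  col <- round(249.5 + (arr$x_mm[3] - ctr[1]) * 100) + 1
  row <- round(249.5 - (arr$y_mm[3] - ctr[2]) * 100) + 1
  delta <- zero
  delta[row, col] <- 99
  amps <- image_to_pulse_amplitudes(delta, arr)
  expect_equal(amps[3], 99)
  expect_equal(amps[-3], rep(0, 19))

  # an array larger than the image is rejected, naming the electrode
  big <- make_electrode_array(20, pitch_mm = 3)
  expect_error(image_to_pulse_amplitudes(uni, big), "e0")
})

test_that("structured trains stack image frames at the pulse rate", {
  arr <- make_electrode_array(20)
  st <- sample_structured_train(12, arr, frequency_hz = 20, seed = 5)
  expect_s3_class(st, "stim_train")
  expect_equal(ncol(st), 20)
  expect_gt(nrow(st), 12 * 3) # static images held ~4 pulses at 20 Hz
  expect_true(all(abs(train_matrix(st)) <= 250))
  expect_identical(train_matrix(st),
                   train_matrix(sample_structured_train(12, arr,
                                                        frequency_hz = 20,
                                                        seed = 5)))
})
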