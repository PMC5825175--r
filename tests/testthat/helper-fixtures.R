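# Shared fixtures, built in code and cached per test run.

circshift_counts <- function(x, s) {
  n <- length(x)
  s <- s %% n
  if (s == 0) return(x)
  c(x[(n - s + 1):n], x[seq_len(n - s)])
}

abs_cosine <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# Small network cell at 10 Hz (L = 3): cheap enough for unit tests.
small_cell <- function(seed = 1, n_pulses = 8000, n_electrodes = 8,
                       n_exc = 1, n_sup = 1, ...) {
  train <- sample_white_noise_train(n_pulses, n_electrodes,
                                    frequency_hz = 10, seed = seed + 1000)
  design <- build_design_matrix(train)
  gt <- make_ground_truth(n_exc, n_sup, L = 3, n_electrodes = n_electrodes,
                          seed = seed, ...)
  resp <- simulate_responses(gt, design, seed = seed + 2000)
  list(train = train, design = design, gt = gt, resp = resp)
}

# Hand-built electrode array with chosen positions (recording site at the
# origin) for geometry-sensitive statistics.
manual_array <- function(x_mm, y_mm) {
  out <- tibble::tibble(
    electrode = sprintf("e%02d", seq_along(x_mm)),
    x_mm = x_mm, y_mm = y_mm
  )
  attr(out, "pitch_mm") <- 1
  attr(out, "diameter_um") <- 400
  attr(out, "recording_loc") <- c(0, 0)
  class(out) <- c("electrode_array", class(out))
  out
}

# The full recovery fixture (60k pulses, 20 electrodes at 20 Hz, 2 exc +
# 1 sup) with a GQM fitted on the first four folds; cached so several
# acceptance checks can share one fit.
.fixture_cache <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (!is.null(.fixture_cache$recovery)) return(.fixture_cache$recovery)
  train <- sample_white_noise_train(60000, 20, seed = 11)
  design <- build_design_matrix(train)
  gt <- make_ground_truth(2, 1, L = 6, n_electrodes = 20, seed = 1)
  resp <- simulate_responses(gt, design, seed = 101)
  folds <- crossval_split(nrow(design), 5)
  test_idx <- folds[[5]]
  train_idx <- setdiff(seq_len(nrow(design)), test_idx)
  model <- fit_gqm(design[train_idx, ], as.numeric(resp)[train_idx],
                   n_exc = 2, n_sup = 1, seed = 1)
  model$L <- attr(design, "L")
  model$n_electrodes <- attr(design, "n_electrodes")
  model$frequency_hz <- attr(design, "frequency_hz")
  preds_te <- predict(model, design[test_idx, ])
  out <- list(
    train = train, design = design, gt = gt, resp = resp,
    model = model, test_idx = test_idx, train_idx = train_idx,
    preds_te = preds_te,
    r2 = coefficient_of_determination(
      binned_prediction_curve(preds_te, as.numeric(resp)[test_idx])),
    best_case = best_case_r2(preds_te, seed = 12)
  )
  .fixture_cache$recovery <- out
  out
}
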