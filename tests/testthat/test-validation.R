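# Independent scalar-loop R^2 for oracle comparison.
ref_r2 <- function(obs, pred) {
  m <- mean(obs)
  ss_tot <- 0; ss_res <- 0
  for (i in seq_along(obs)) {
    ss_tot <- ss_tot + (obs[i] - m)^2
    ss_res <- ss_res + (obs[i] - pred[i])^2
  }
  1 - ss_res / ss_tot
}

test_that("contiguous folds partition the rows exactly once", {
  folds <- crossval_split(100, 5)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 20))
  expect_equal(sort(unlist(folds)), 1:100)
  for (i in 1:4) expect_length(intersect(folds[[i]], folds[[i + 1]]), 0)
  # blocks are contiguous
  expect_true(all(vapply(folds, function(f) all(diff(f) == 1), logical(1))))
  folds2 <- crossval_split(103, 5)
  expect_equal(sort(unlist(folds2)), 1:103)
  expect_error(crossval_split(100, 1), "k")
  expect_error(crossval_split(3, 5), "fewer rows")
})

test_that("binned prediction curves are exact bin statistics", {
  set.seed(41)
  preds <- runif(450, 0, 3)
  # noise-free: observations equal predictions bin by bin
  b <- binned_prediction_curve(preds, preds, bin_size = 200)
  expect_equal(nrow(b), 2) # partial third bin dropped
  expect_equal(b$obs_mean, b$pred_mean)
  # hand recomputation of the first bin
  counts <- rpois(450, preds)
  b2 <- binned_prediction_curve(preds, counts, bin_size = 200)
  ord <- order(preds)
  expect_equal(b2$obs_mean[1], mean(counts[ord[1:200]]))
  expect_equal(b2$obs_var[1], var(counts[ord[1:200]]))
  expect_equal(b2$obs_se[1], sd(counts[ord[1:200]]) / sqrt(200))
  expect_error(binned_prediction_curve(preds[1:100], counts[1:100], 200),
               "fewer rows")
})

test_that("coefficient of determination matches the reference formula", {
  b <- tibble::tibble(pred_mean = 1:10, obs_mean = 1:10)
  expect_equal(coefficient_of_determination(b), 1)
  set.seed(42)
  for (rep in 1:20) {
    obs <- rnorm(30); pred <- rnorm(30)
    bb <- tibble::tibble(pred_mean = pred, obs_mean = obs)
    expect_equal(coefficient_of_determination(bb), ref_r2(obs, pred),
                 tolerance = 1e-12)
  }
  expect_warning(
    out <- coefficient_of_determination(
      tibble::tibble(pred_mean = 1:3, obs_mean = rep(1, 3))),
    "zero variance"
  )
  expect_true(is.na(out))
})

test_that("the Poisson best-case ceiling behaves as a ceiling", {
  set.seed(43)
  preds <- rexp(20000, 1)
  expect_warning(best_case_r2(rep(2, 1000), bin_size = 100), "constant")
  # huge bins average the noise away
  expect_gt(best_case_r2(preds, bin_size = 5000, n_sims = 10, seed = 1),
            0.97)
  # realized R^2 of Poisson data does not beat the ceiling by more than
  # Monte-Carlo error
  counts <- rpois(20000, preds)
  real <- coefficient_of_determination(
    binned_prediction_curve(preds, counts, 200))
  ceiling <- best_case_r2(preds, 200, n_sims = 20, seed = 2)
  expect_lt(real, ceiling + 0.03)
})

test_that("variance-vs-mean slope diagnoses Poisson spiking", {
  set.seed(44)
  preds <- runif(30000, 0.05, 3)
  counts <- rpois(30000, preds)
  b <- binned_prediction_curve(preds, counts, 200)
  vm <- variance_mean_check(b)
  expect_gt(vm$slope, 0.85); expect_lt(vm$slope, 1.15)
  # deterministic counts have zero variance
  bd <- binned_prediction_curve(preds, round(preds * 0) + 2, 200)
  expect_equal(variance_mean_check(bd)$slope, 0)
  # normalization makes the slope scale-free
  b2 <- binned_prediction_curve(2 * preds, rpois(30000, 2 * preds), 200)
  vm2 <- variance_mean_check(b2)
  expect_equal(vm2$slope, vm$slope, tolerance = 0.15)
})

test_that("cross-validated metrics are fold averages with exact bookkeeping", {
  fx <- small_cell(seed = 45, n_pulses = 6000, n_electrodes = 6)
  val <- validate_model(
    fx$design, fx$resp,
    fit_fun = function(d, r) fit_gqm(d, r, 1, 0, seed = 1,
                                     control = gqm_control(max_outer = 3)),
    k = 5, bin_size = 100, n_sims = 5, seed = 9
  )
  expect_equal(nrow(val$per_fold), 5)
  expect_equal(val$r2, mean(val$per_fold$r2))
  expect_equal(val$avg_error_spikes, mean(val$per_fold$avg_error_spikes))
  expect_equal(sort(unlist(val$folds)), seq_len(nrow(fx$design)))
  # error definitions: mean |pred - obs| per bin, then % of max response
  one <- dplyr::filter(val$binned, fold == 1)
  expect_equal(val$per_fold$avg_error_spikes[1],
               mean(abs(one$pred_mean - one$obs_mean)))
  expect_equal(val$per_fold$pct_error[1],
               val$per_fold$avg_error_spikes[1] / max(one$obs_mean) * 100)
  expect_s3_class(glance(val), "tbl_df")
})
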