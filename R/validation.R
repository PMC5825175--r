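#' Contiguous k-fold split for time-structured responses
#'
#' Partitions row indices into `k` contiguous, near-equal blocks.  Blocks
#' (rather than random interleaving) are used because neighbouring design
#' rows share overlapping stimulus histories, which would leak across a
#' random split.
#'
#' @param n_rows Number of rows.
#' @param k Number of folds (>= 2).
#' @param seed Unused for the contiguous scheme (kept for interface
#'   stability with randomized splitters).
#' @return List of `k` integer index vectors, disjoint, covering all rows.
#' @export
crossval_split <- function(n_rows, k = 5, seed = 1) {
  n_rows <- check_count(n_rows, "n_rows")
  k <- check_count(k, "k", min = 2)
  if (n_rows < k) abort("fewer rows than folds.")
  bounds <- round(seq(0, n_rows, length.out = k + 1))
  lapply(seq_len(k), function(i) seq.int(bounds[i] + 1L, bounds[i + 1L]))
}

#' Bin held-out responses along the model prediction
#'
#' Sorts rows by predicted spike count (stable sort, so tied predictions
#' keep their temporal order), forms contiguous bins of `bin_size` stimuli
#' (final partial bin dropped), and reports per-bin mean prediction and the
#' mean, standard error and variance of the observed counts.
#'
#' @param preds Predicted spike counts per row.
#' @param counts Observed spike counts per row.
#' @param bin_size Stimuli per bin.
#' @return Tibble with `pred_mean`, `obs_mean`, `obs_se`, `obs_var`, `n`.
#' @export
binned_prediction_curve <- function(preds, counts, bin_size = 200) {
  preds <- as.numeric(preds); counts <- as.numeric(counts)
  if (length(preds) != length(counts)) abort("length mismatch.")
  if (length(preds) < bin_size) abort("fewer rows than one bin.")
  b <- bin_by(preds, counts, bin_size)
  tibble::tibble(pred_mean = b$g_mean, obs_mean = b$response_mean,
                 obs_se = b$response_se, obs_var = b$response_var, n = b$n)
}

#' Coefficient of determination between binned observation and prediction
#'
#' `R^2 = 1 - SS_res / SS_tot` of the per-bin observed means against the
#' per-bin mean predictions.  Can be negative when the prediction does worse
#' than the constant mean; `NA` (flagged by a warning) when the observed
#' means have zero variance.
#'
#' @param binned A tibble from [binned_prediction_curve()].
#' @return Scalar R-squared.
#' @export
coefficient_of_determination <- function(binned) {
  if (nrow(binned) < 2) abort("need at least two bins.")
  obs <- binned$obs_mean; pred <- binned$pred_mean
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warn("observed bin means have zero variance; R^2 undefined.")
    return(NA_real_)
  }
  1 - sum((obs - pred)^2) / ss_tot
}

#' Best-case R-squared under Poisson spiking variability
#'
#' The ceiling a perfect model could reach given Poisson noise: counts are
#' simulated as Poisson draws with mean equal to the prediction, binned
#' identically, and the resulting R-squared is averaged over `n_sims`
#' simulations.
#'
#' @inheritParams binned_prediction_curve
#' @param n_sims Number of Poisson simulations.
#' @param seed Integer seed.
#' @return Mean simulated R-squared.
#' @export
best_case_r2 <- function(preds, bin_size = 200, n_sims = 20, seed = 1) {
  preds <- as.numeric(preds)
  if (all(preds <= 0)) abort("all predictions are zero.")
  if (max(preds) - min(preds) < sqrt(.Machine$double.eps)) {
    warn("constant predictions: best-case R^2 undefined.")
    return(NA_real_)
  }
  with_seed(derive_seed(seed, "best_case"), {
    mean(vapply(seq_len(n_sims), function(i) {
      sim <- rpois(length(preds), preds)
      coefficient_of_determination(
        binned_prediction_curve(preds, sim, bin_size))
    }, numeric(1)))
  })
}

#' Variance-versus-mean diagnostic for Poisson spiking
#'
#' Normalizes per-bin observed variance and mean prediction by the maximum
#' prediction and fits a through-origin regression.  For Poisson-like
#' spiking the variance equals the mean, so the slope is ~1.
#'
#' @param binned A tibble from [binned_prediction_curve()].
#' @param max_pred Normalizing constant; defaults to the maximum bin
#'   prediction.
#' @return List with `points` (tibble `mean_norm`, `var_norm`) and `slope`.
#' @export
variance_mean_check <- function(binned, max_pred = max(binned$pred_mean)) {
  if (nrow(binned) < 2) abort("need at least two bins.")
  x <- binned$pred_mean / max_pred
  y <- binned$obs_var / max_pred
  slope <- if (sum(x^2) == 0) 0 else sum(x * y) / sum(x^2)
  list(points = tibble::tibble(mean_norm = x, var_norm = y), slope = slope)
}

#' Cross-validated prediction diagnostics for a model family
#'
#' Runs the full validation loop: contiguous 5-fold split, fit on four
#' folds, predict the held-out fold, bin the held-out predictions, and
#' report fold-averaged metrics: R-squared, the simulated Poisson best-case
#' R-squared, the mean absolute bin error in spikes, the same as a
#' percentage of the maximum response, and the variance-vs-mean slope.
#'
#' @param design An `erf_design`.
#' @param resp Aligned spike counts.
#' @param fit_fun `function(design_train, resp_train)` returning an object
#'   with a `predict(object, newdata)` method (e.g. a wrapper around
#'   [fit_gqm()]).
#' @param k Number of folds.
#' @param bin_size Stimuli per bin.
#' @param n_sims Poisson simulations for the best-case ceiling.
#' @param seed Integer seed.
#' @param folds_to_use Which folds serve as validation sets (default all).
#' @return An object of class `erf_validation`: list with `binned` (tibble,
#'   per fold), `per_fold` (tibble of per-fold metrics), and fold-averaged
#'   `r2`, `r2_best_case`, `avg_error_spikes`, `pct_error`,
#'   `variance_slope`.
#' @export
validate_model <- function(design, resp, fit_fun, k = 5, bin_size = 200,
                           n_sims = 20, seed = 1,
                           folds_to_use = seq_len(k)) {
  r <- as.numeric(resp)
  folds <- crossval_split(nrow(design), k = k, seed = seed)
  rows <- list(); metrics <- list()
  for (i in folds_to_use) {
    test_idx <- folds[[i]]
    train_idx <- setdiff(seq_len(nrow(design)), test_idx)
    model <- fit_fun(subset_design(design, train_idx), r[train_idx])
    preds <- predict(model, subset_design(design, test_idx))
    binned <- binned_prediction_curve(preds, r[test_idx], bin_size)
    r2 <- coefficient_of_determination(binned)
    bc <- best_case_r2(preds, bin_size, n_sims, seed = derive_seed(seed, i))
    vm <- variance_mean_check(binned)
    avg_err <- mean(abs(binned$pred_mean - binned$obs_mean))
    pct_err <- avg_err / max(binned$obs_mean) * 100
    rows[[length(rows) + 1]] <- dplyr::mutate(binned, fold = i)
    metrics[[length(metrics) + 1]] <- tibble::tibble(
      fold = i, r2 = r2, r2_best_case = bc, avg_error_spikes = avg_err,
      pct_error = pct_err, variance_slope = vm$slope
    )
  }
  per_fold <- dplyr::bind_rows(metrics)
  structure(list(
    binned = dplyr::bind_rows(rows),
    per_fold = per_fold,
    folds = folds,
    r2 = mean(per_fold$r2),
    r2_best_case = mean(per_fold$r2_best_case),
    avg_error_spikes = mean(per_fold$avg_error_spikes),
    pct_error = mean(per_fold$pct_error),
    variance_slope = mean(per_fold$variance_slope)
  ), class = "erf_validation")
}

subset_design <- function(design, idx) {
  X <- unclass_design(design)[idx, , drop = FALSE]
  if (!is.null(attr(design, "L"))) {
    X <- new_erf_design(X, L = attr(design, "L"),
                        n_electrodes = attr(design, "n_electrodes"),
                        frequency_hz = attr(design, "frequency_hz"),
                        window_ms = attr(design, "window_ms"))
  }
  X
}

#' @export
print.erf_validation <- function(x, ...) {
  cat(sprintf(
    "<erf_validation> %d folds: R2 %.3f (best case %.3f), %.3f spikes/bin error (%.1f%%), variance slope %.2f\n",
    nrow(x$per_fold), x$r2, x$r2_best_case, x$avg_error_spikes, x$pct_error,
    x$variance_slope
  ))
  invisible(x)
}

#' @describeIn validate_model One-row tibble of fold-averaged metrics.
#' @param x An `erf_validation`.
#' @param ... Unused.
#' @method glance erf_validation
#' @export
glance.erf_validation <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, r2_best_case = x$r2_best_case,
    avg_error_spikes = x$avg_error_spikes, pct_error = x$pct_error,
    variance_slope = x$variance_slope, n_folds = nrow(x$per_fold)
  )
}
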