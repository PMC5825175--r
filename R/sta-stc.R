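#' Spike-triggered average
#'
#' Spike-count-weighted mean of the design rows: the average stimulus
#' history that preceded a spike.
#'
#' @param design An `erf_design` (or matrix), rows = stimulus histories.
#' @param resp A `spike_response` (or integer vector) aligned to the rows.
#' @return Numeric filter vector of length `ncol(design)`.
#' @export
compute_sta <- function(design, resp) {
  X <- unclass_design(design)
  r <- as.numeric(resp)
  if (length(r) != nrow(X)) abort("response length does not match design rows.")
  n_sp <- sum(r)
  if (n_sp <= 0) abort("no spikes: the spike-triggered ensemble is empty.")
  as.numeric(crossprod(X, r)) / n_sp
}

#' Spike-triggered covariance analysis
#'
#' Eigendecomposition of the spike-count-weighted covariance of the design
#' rows about the spike-triggered average.  Because the stimulus is white
#' with equal per-electrode variance, directions whose spike-triggered
#' variance is raised (excitatory) or lowered (suppressive) relative to the
#' raw ensemble appear as extreme eigenvalues; significance is judged
#' against a shuffle null (see [eigenvalue_null_ci()]).
#'
#' @inheritParams compute_sta
#' @param null_ci Optional result of [eigenvalue_null_ci()]; when supplied,
#'   per-rank significance is filled in.
#' @return An object of class `stc_result`: list with `sta`, `eigenvalues`
#'   (sorted descending), `eigenvectors` (orthonormal columns, sign fixed so
#'   the largest-magnitude entry is positive), `null_lo`, `null_hi`,
#'   `significant_exc`, `significant_sup`, `n_spikes`.
#' @export
compute_stc <- function(design, resp, null_ci = NULL) {
  X <- unclass_design(design)
  r <- as.numeric(resp)
  if (anyNA(X) || anyNA(r)) abort("NAs in design or response.")
  if (length(r) != nrow(X)) abort("response length does not match design rows.")
  n_sp <- sum(r)
  if (n_sp <= 0) abort("no spikes: the spike-triggered ensemble is empty.")
  if (n_sp <= ncol(X)) {
    warn("fewer spikes than stimulus dimensions; STC will be rank deficient.")
  }
  sta <- as.numeric(crossprod(X, r)) / n_sp
  Xc <- sweep(X, 2, sta)
  C <- crossprod(Xc * sqrt(r / n_sp)) # weighted covariance about the STA
  eg <- eigen(C, symmetric = TRUE)
  vec <- eg$vectors
  # deterministic sign: largest-|entry| coordinate positive
  for (j in seq_len(ncol(vec))) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  out <- structure(list(
    sta = sta,
    eigenvalues = eg$values,
    eigenvectors = vec,
    null_lo = NULL, null_hi = NULL,
    significant_exc = integer(), significant_sup = integer(),
    n_spikes = n_sp,
    L = attr(design, "L"), n_electrodes = attr(design, "n_electrodes"),
    frequency_hz = attr(design, "frequency_hz")
  ), class = "stc_result")
  if (!is.null(null_ci)) out <- apply_null_ci(out, null_ci)
  out
}

apply_null_ci <- function(stc, null_ci) {
  stc$null_lo <- null_ci$null_lo
  stc$null_hi <- null_ci$null_hi
  stc$significant_exc <- which(stc$eigenvalues > null_ci$null_hi)
  stc$significant_sup <- which(stc$eigenvalues < null_ci$null_lo)
  stc
}

#' Shuffle-null confidence bounds for STC eigenvalues
#'
#' Builds the null distribution of the STC eigenvalue spectrum by circularly
#' time-shifting the response vector by random offsets of at least `L` rows
#' (preserving response autocorrelation while destroying stimulus-response
#' alignment) and recomputing the eigendecomposition.  Per-rank
#' (`alpha/2`, `1 - alpha/2`) quantiles form the confidence band; with the
#' default `alpha = 0.05` these are the 2.5 and 97.5 percentiles.
#' Eigenvalues above the band are significant excitatory directions, below
#' it significant suppressive ones.
#'
#' @inheritParams compute_sta
#' @param n_shuffles Number of circular shifts (>= 100).
#' @param alpha Two-sided significance level.
#' @param seed Integer seed.
#' @return List with `null_lo`, `null_hi` (per rank), `alpha`, `n_shuffles`.
#' @export
eigenvalue_null_ci <- function(design, resp, n_shuffles = 500, alpha = 0.05,
                               seed = 1) {
  n_shuffles <- check_count(n_shuffles, "n_shuffles", min = 100)
  X <- unclass_design(design)
  r <- as.numeric(resp)
  L <- attr(design, "L") %||% 1L
  n <- nrow(X)
  if (n < 2 * L) abort("record too short for circular shifts of at least L.")
  if (sum(r) <= 0) abort("no spikes: the spike-triggered ensemble is empty.")
  vals <- with_seed(derive_seed(seed, "eig_null"), {
    shifts <- sample.int(n - 2L * L + 1L, n_shuffles, replace = TRUE) + L - 1L
    vapply(shifts, function(s) {
      stc_eigenvalues(X, circular_shift(r, s))
    }, numeric(ncol(X)))
  })
  list(
    null_lo = apply(vals, 1, quantile, probs = alpha / 2, names = FALSE),
    null_hi = apply(vals, 1, quantile, probs = 1 - alpha / 2, names = FALSE),
    alpha = alpha, n_shuffles = n_shuffles
  )
}

circular_shift <- function(x, s) {
  n <- length(x)
  s <- s %% n
  if (s == 0) return(x)
  c(x[(n - s + 1):n], x[seq_len(n - s)])
}

stc_eigenvalues <- function(X, r) {
  n_sp <- sum(r)
  sta <- as.numeric(crossprod(X, r)) / n_sp
  Xc <- sweep(X, 2, sta)
  C <- crossprod(Xc * sqrt(r / n_sp))
  eigen(C, symmetric = TRUE, only.values = TRUE)$values
}

#' Run STA/STC with shuffle-null significance in one call
#' @inheritParams eigenvalue_null_ci
#' @return An `stc_result` with the null band and significant ranks set.
#' @export
stc_analysis <- function(design, resp, n_shuffles = 500, alpha = 0.05,
                         seed = 1) {
  ci <- eigenvalue_null_ci(design, resp, n_shuffles = n_shuffles,
                           alpha = alpha, seed = seed)
  compute_stc(design, resp, null_ci = ci)
}

#' @export
print.stc_result <- function(x, ...) {
  cat(sprintf(
    "<stc_result> %d eigenvalues, %d spikes; significant: %d excitatory, %d suppressive\n",
    length(x$eigenvalues), x$n_spikes, length(x$significant_exc),
    length(x$significant_sup)
  ))
  invisible(x)
}

#' @describeIn compute_stc Tidy the eigenvalue spectrum into a tibble with
#'   per-rank null bounds and significance class.
#' @param x An `stc_result`.
#' @param ... Unused.
#' @method tidy stc_result
#' @export
tidy.stc_result <- function(x, ...) {
  n <- length(x$eigenvalues)
  tibble::tibble(
    rank = seq_len(n),
    eigenvalue = x$eigenvalues,
    null_lo = x$null_lo %||% rep(NA_real_, n),
    null_hi = x$null_hi %||% rep(NA_real_, n),
    significance = dplyr::case_when(
      seq_len(n) %in% x$significant_exc ~ "excitatory",
      seq_len(n) %in% x$significant_sup ~ "suppressive",
      .default = "none"
    )
  )
}
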