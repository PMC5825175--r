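#' Build the windowed stimulus design matrix
#'
#' Expands a pulse train into per-response stimulus-history rows.  Row `t`
#' concatenates the pulse-amplitude vectors at lags 0 .. L-1 (lag 0 = the
#' pulse immediately preceding the response bin), with column ordering
#' lag-major, electrode-minor: `[lag0 e01..eNN, lag1 e01..eNN, ...]`.
#' The number of lags is `L = round(window_ms * frequency_hz / 1000)`; the
#' default 300 ms window is a conservative bound on the period over which
#' the retina integrates stimulation history.  The first `L - 1` pulses have
#' incomplete history and produce no rows, so the matrix has
#' `n_pulses - L + 1` rows; row `r` corresponds to pulse `r + L - 1`.
#'
#' @param train A `stim_train` (or numeric matrix, pulses x electrodes; then
#'   `frequency_hz` must be supplied).
#' @param window_ms Stimulus-history window, ms; must cover at least one
#'   inter-pulse interval.
#' @param frequency_hz Pulse rate; defaults to the train's attribute.
#'
#' @return A numeric matrix of class `erf_design` with attributes `L`,
#'   `n_electrodes`, `frequency_hz`, `window_ms` and `lag_times_ms`
#'   (0, -1000/f, -2000/f, ...; lag 0 is the most recent pulse).
#' @examples
#' tr <- sample_white_noise_train(100, 4, frequency_hz = 10, seed = 1)
#' X <- build_design_matrix(tr)   # L = 3 at 10 Hz, 98 rows
#' @export
build_design_matrix <- function(train, window_ms = 300, frequency_hz = NULL) {
  freq <- frequency_hz %||% attr(train, "frequency_hz")
  if (is.null(freq)) abort("`frequency_hz` not supplied and not on `train`.")
  freq <- check_positive(freq, "frequency_hz")
  window_ms <- check_positive(window_ms, "window_ms")
  if (window_ms < 1000 / freq) {
    abort("`window_ms` is shorter than one inter-pulse interval.")
  }
  A <- if (inherits(train, "stim_train")) train_matrix(train) else
    unname(as.matrix(train))
  if (anyNA(A)) abort("stimulus train contains missing values.")
  L <- max(1L, as.integer(round(window_ms * freq / 1000)))
  if (nrow(A) < L) abort("fewer pulses than lags in the history window.")

  # embed() yields exactly the (lag-major, electrode-minor) layout
  X <- stats::embed(A, L)
  new_erf_design(X, L = L, n_electrodes = ncol(A), frequency_hz = freq,
                 window_ms = window_ms)
}

new_erf_design <- function(X, L, n_electrodes, frequency_hz, window_ms = NA) {
  attr(X, "L") <- as.integer(L)
  attr(X, "n_electrodes") <- as.integer(n_electrodes)
  attr(X, "frequency_hz") <- frequency_hz
  attr(X, "window_ms") <- window_ms
  attr(X, "lag_times_ms") <- -(seq_len(L) - 1) * 1000 / frequency_hz
  class(X) <- c("erf_design", class(X))
  X
}

#' Recover the pulse rows encoded in one design-matrix row
#' @param design An `erf_design`.
#' @param row Row index.
#' @return Matrix L x n_electrodes; row 1 is lag 0 (most recent pulse).
#' @export
design_row_history <- function(design, row) {
  L <- attr(design, "L")
  ne <- attr(design, "n_electrodes")
  matrix(design[row, ], nrow = L, ncol = ne, byrow = TRUE)
}

#' Align per-pulse spike counts to design-matrix rows
#'
#' The response bin for a design row is the inter-pulse interval following
#' its lag-0 pulse, so the first `L - 1` per-pulse counts are dropped.
#'
#' @param counts Integer vector of spike counts, one per pulse.
#' @param design An `erf_design` built from the same train.
#' @return Integer vector with one count per design row.
#' @export
align_responses <- function(counts, design) {
  L <- attr(design, "L")
  if (length(counts) != nrow(design) + L - 1) {
    abort("`counts` length does not match the pulse count of the design.")
  }
  counts[seq.int(L, length(counts))]
}

#' @export
print.erf_design <- function(x, ...) {
  cat(sprintf(
    "<erf_design> %d responses x (%d lags x %d electrodes) at %g Hz\n",
    nrow(x), attr(x, "L"), attr(x, "n_electrodes"), attr(x, "frequency_hz")
  ))
  invisible(x)
}
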