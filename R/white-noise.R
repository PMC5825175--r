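#' Sample a Gaussian white-noise pulse-amplitude train
#'
#' Draws per-pulse, per-electrode biphasic pulse amplitudes (in uA, positive =
#' anodic-first) i.i.d. from a zero-mean Gaussian with standard deviation
#' `sigma_ua`, rejection-resampling any draw whose magnitude exceeds the
#' stimulator limit `limit_ua`.  Defaults match the recorded stimulation
#' protocol: sigma = 150 uA, limits +/-300 uA.
#'
#' @param n_pulses Number of pulses.
#' @param n_electrodes Number of electrodes.
#' @param sigma_ua Gaussian standard deviation of amplitudes, uA.
#' @param limit_ua Stimulator limit, uA; draws beyond +/-`limit_ua` are
#'   discarded and redrawn (truncation by rejection, not clipping).
#' @param frequency_hz Pulse rate in Hz (10, 20 or 30 in the recordings, any
#'   positive rate accepted).
#' @param seed Integer seed; identical seeds give identical trains.
#'
#' @return A tibble of class `stim_train`, one row per pulse, columns
#'   `e01` ... `eNN` in uA, with attributes `frequency_hz`, `sigma_ua`,
#'   `limit_ua`, `seed`.
#' @examples
#' tr <- sample_white_noise_train(1000, 4, seed = 1)
#' sd(as.matrix(tr))  # ~132 uA: truncation at 2 sigma shrinks the SD
#' @export
sample_white_noise_train <- function(n_pulses, n_electrodes = 20,
                                     sigma_ua = 150, limit_ua = 300,
                                     frequency_hz = 20, seed = 1) {
  n_pulses <- check_count(n_pulses, "n_pulses")
  n_electrodes <- check_count(n_electrodes, "n_electrodes")
  sigma <- check_positive(sigma_ua, "sigma_ua")
  limit <- check_positive(limit_ua, "limit_ua")
  freq <- check_positive(frequency_hz, "frequency_hz")
  if (limit < sigma / 100) {
    warn("`limit_ua` is far below `sigma_ua`; truncation is nearly degenerate.")
  }

  amp <- with_seed(derive_seed(seed, "white_noise"), {
    x <- rnorm(n_pulses * n_electrodes, 0, sigma)
    bad <- which(abs(x) > limit)
    while (length(bad) > 0) {
      x[bad] <- rnorm(length(bad), 0, sigma)
      bad <- bad[abs(x[bad]) > limit]
    }
    matrix(x, n_pulses, n_electrodes)
  })
  new_stim_train(amp, frequency_hz = freq, sigma_ua = sigma,
                 limit_ua = limit, seed = seed)
}

new_stim_train <- function(amplitudes, frequency_hz, sigma_ua = NA_real_,
                           limit_ua = NA_real_, seed = NA_integer_) {
  amplitudes <- as.matrix(amplitudes)
  colnames(amplitudes) <- sprintf("e%02d", seq_len(ncol(amplitudes)))
  out <- tibble::as_tibble(amplitudes)
  attr(out, "frequency_hz") <- frequency_hz
  attr(out, "sigma_ua") <- sigma_ua
  attr(out, "limit_ua") <- limit_ua
  attr(out, "seed") <- seed
  class(out) <- c("stim_train", class(out))
  out
}

#' Stimulus-train pulse amplitudes as a matrix
#' @param train A `stim_train`.
#' @return Numeric matrix, pulses x electrodes, uA.
#' @export
train_matrix <- function(train) {
  unname(as.matrix(as.data.frame(train)))
}

#' Closed-form standard deviation of a symmetrically truncated Gaussian
#'
#' SD of a N(0, sigma^2) variable conditioned on |x| <= limit:
#' `sigma * sqrt(1 - 2 * alpha * dnorm(alpha) / (2 * pnorm(alpha) - 1))`
#' with `alpha = limit / sigma`.  For the protocol values (150, 300) this is
#' ~131.9 uA.
#'
#' @param sigma_ua Untruncated Gaussian SD, uA.
#' @param limit_ua Symmetric truncation bound, uA.
#' @return Standard deviation in uA.
#' @export
truncated_gaussian_sd <- function(sigma_ua = 150, limit_ua = 300) {
  a <- limit_ua / sigma_ua
  sigma_ua * sqrt(1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1))
}

#' CDF of the symmetrically truncated Gaussian amplitude distribution
#' @inheritParams truncated_gaussian_sd
#' @param q Quantiles, uA.
#' @return Probabilities.
#' @export
truncated_gaussian_cdf <- function(q, sigma_ua = 150, limit_ua = 300) {
  a <- limit_ua / sigma_ua
  z <- pmin(pmax(q / sigma_ua, -a), a)
  (pnorm(z) - pnorm(-a)) / (2 * pnorm(a) - 1)
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf(
    "<stim_train> %d pulses x %d electrodes at %g Hz (sigma %g uA, limit %g uA)\n",
    nrow(x), ncol(x), attr(x, "frequency_hz"), attr(x, "sigma_ua"),
    attr(x, "limit_ua")
  ))
  NextMethod()
}
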