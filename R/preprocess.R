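#' Signal-to-noise ratio of a spike waveform
#'
#' `SNR = (max(W) - min(W)) / (2 * noise_sd)`: peak-to-peak amplitude of the
#' mean spike waveform over twice the waveform-noise SD.  Recordings with
#' SNR below 4 are conventionally discarded.
#'
#' @param mean_waveform Numeric vector, the average spike time-course (uV).
#' @param noise_sd Standard deviation of the waveform noise (uV, > 0).
#' @return List with `snr` and `keep` (`snr >= 4`).
#' @export
snr <- function(mean_waveform, noise_sd) {
  if (length(mean_waveform) == 0) abort("empty waveform.")
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort("`noise_sd` must be positive.")
  }
  val <- (max(mean_waveform) - min(mean_waveform)) / (2 * noise_sd)
  list(snr = val, keep = val >= 4)
}

#' Classify a cell as ON, OFF, ON-OFF or unclassified from light steps
#'
#' Compares spike rates between alternating light-on and light-off periods
#' and the transient rates in the 1 s window after each transition.  A
#' transient is called significant when a one-way ANOVA finds it elevated
#' above the steady rate of the period it interrupts.  Decision rule
#' (transients take precedence over steady rates): both transients
#' significant gives ON-OFF; otherwise a significant on-transient or
#' significantly higher on-rate gives ON, the mirror case gives OFF; else
#' the cell stays unclassified.  The classification is invariant to uniform
#' rate scaling.
#'
#' @param light A data frame with one row per stimulus repeat and columns
#'   `on_rate`, `off_rate` (steady spikes/s) and `on_transient`,
#'   `off_transient` (spikes/s in the 1 s window after the transition to
#'   light / to dark).
#' @param alpha Significance level for the ANOVA comparisons.
#' @return A single string: `"ON"`, `"OFF"`, `"ON_OFF"` or
#'   `"UNCLASSIFIED"`.
#' @export
classify_light_response <- function(light, alpha = 0.05) {
  need <- c("on_rate", "off_rate", "on_transient", "off_transient")
  if (!all(need %in% names(light))) {
    abort(sprintf("`light` must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (nrow(light) < 2) {
    warn("fewer than 2 repeats; cell left unclassified.")
    return("UNCLASSIFIED")
  }
  higher <- function(a, b) {
    # one-way ANOVA between the two groups; direction checked on the means
    if (mean(a) <= mean(b)) return(FALSE)
    if (sd(c(a, b)) == 0) return(FALSE)
    df <- data.frame(y = c(a, b),
                     grp = rep(c("a", "b"), c(length(a), length(b))))
    p <- anova(aov(y ~ grp, data = df))[["Pr(>F)"]][1]
    is.finite(p) && p < alpha
  }
  on_trans <- higher(light$on_transient, light$off_rate)
  off_trans <- higher(light$off_transient, light$on_rate)
  on_rate <- higher(light$on_rate, light$off_rate)
  off_rate <- higher(light$off_rate, light$on_rate)
  if (on_trans && off_trans) return("ON_OFF")
  if (on_trans || on_rate) return("ON")
  if (off_trans || off_rate) return("OFF")
  "UNCLASSIFIED"
}
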