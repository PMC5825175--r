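#' Tidy a fitted GQM into a long coefficient table
#'
#' One row per (filter, lag, electrode) coefficient, covering `v0` and every
#' quadratic component, with lag times in ms and the bootstrap significance
#' flag when available.
#'
#' @param x A `gqm`.
#' @param ... Unused.
#' @return Tibble with columns `filter`, `class`, `lag`, `lag_ms`,
#'   `electrode`, `coefficient`, `significant`.
#' @method tidy gqm
#' @export
tidy.gqm <- function(x, ...) {
  ne <- x$n_electrodes %||% length(x$v0)
  L <- x$L %||% (length(x$v0) / ne)
  f <- x$frequency_hz %||% NA_real_
  base <- tidyr::expand_grid(lag = seq_len(L) - 1L,
                             electrode = seq_len(ne))
  one <- function(name, class, v, sig) {
    dplyr::mutate(base, filter = name, class = class,
                  lag_ms = -.data$lag * 1000 / f,
                  coefficient = v,
                  significant = sig %||% NA)
  }
  rows <- list(one("v0", "linear", x$v0, x$sig_mask$v0))
  for (i in seq_len(ncol(x$V))) {
    rows[[i + 1]] <- one(
      sprintf("v%d", i),
      if (x$w[i] > 0) "excitatory" else "suppressive",
      x$V[, i],
      if (!is.null(x$sig_mask)) x$sig_mask$components[, i]
    )
  }
  dplyr::select(dplyr::bind_rows(rows),
                "filter", "class", "lag", "lag_ms", "electrode",
                "coefficient", "significant")
}

#' One-row summary of a fitted GQM
#' @param x A `gqm`.
#' @param ... Unused.
#' @return Tibble with the component counts, sigmoid parameters, component
#'   norms and fit diagnostics.
#' @method glance gqm
#' @export
glance.gqm <- function(x, ...) {
  tibble::tibble(
    n_exc = x$n_exc, n_sup = x$n_sup,
    sigmoid_a = x$sigmoid[["a"]], sigmoid_b = x$sigmoid[["b"]],
    sigmoid_c = x$sigmoid[["c"]],
    v0_norm = sqrt(sum(x$v0^2)),
    loglik = x$fit_meta$loglik %||% NA_real_,
    iterations = x$fit_meta$iterations %||% NA_integer_,
    converged = x$fit_meta$converged %||% NA
  )
}

#' Plot the spatiotemporal filters of a fitted GQM
#'
#' Electrode-by-lag amplitude maps, one facet per filter, significant
#' entries outlined.
#'
#' @param object A `gqm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gqm
#' @export
autoplot.gqm <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$electrode, y = factor(.data$lag_ms),
    fill = .data$coefficient
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  mid = "white") +
    ggplot2::facet_wrap(~ filter + class, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "electrode", y = "lag (ms)", fill = "amplitude",
                  title = "Electrical receptive-field components")
  if (!all(is.na(df$significant))) {
    p <- p + ggplot2::geom_tile(
      data = dplyr::filter(df, .data$significant %in% TRUE),
      fill = NA, colour = "black", linewidth = 0.6
    )
  }
  p
}

#' Plot an STC eigenvalue spectrum against its shuffle-null band
#' @param object An `stc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stc_result
#' @export
autoplot.stc_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                        y = .data$eigenvalue))
  if (!all(is.na(df$null_lo))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$null_lo, ymax = .data$null_hi),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significance),
                        size = 1) +
    ggplot2::scale_colour_manual(values = c(
      excitatory = "#b2182b", suppressive = "#2166ac", none = "grey30"
    )) +
    ggplot2::labs(x = "rank", y = "eigenvalue",
                  title = "STC eigenvalues vs shuffle null")
}

#' Plot held-out predictions against binned observed responses
#' @param object An `erf_validation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erf_validation
#' @export
autoplot.erf_validation <- function(object, ...) {
  ggplot2::ggplot(object$binned,
                  ggplot2::aes(x = .data$pred_mean, y = .data$obs_mean)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$obs_mean - .data$obs_se,
      ymax = .data$obs_mean + .data$obs_se
    ), size = 0.2) +
    ggplot2::facet_wrap(~ fold) +
    ggplot2::labs(x = "predicted spikes/bin",
                  y = "observed spikes/bin (200-stimulus bins)",
                  title = sprintf("Held-out prediction (R² = %.2f)",
                                  object$r2))
}

#' Plot a fitted output nonlinearity over its binned data
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sigmoid_fit
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  b <- object$binned_curve
  xs <- seq(min(b$g_mean), max(b$g_mean), length.out = 200)
  curve <- tibble::tibble(
    g = xs,
    fit = if (object$flat) rep(object$a, length(xs)) else
      object$a / (1 + exp(-object$b * (xs - object$c)))
  )
  ggplot2::ggplot(b, ggplot2::aes(x = .data$g_mean,
                                  y = .data$response_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$response_mean - .data$response_se,
      ymax = .data$response_mean + .data$response_se
    ), colour = "#b2182b", size = 0.2) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$g, y = .data$fit)) +
    ggplot2::labs(x = "generator signal", y = "spikes/bin",
                  title = "Output nonlinearity (200-stimulus bins)")
}
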