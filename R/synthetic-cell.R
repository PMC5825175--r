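#' Construct a ground-truth synthetic cell
#'
#' Builds a known Generalized Quadratic Model cell for end-to-end testing:
#' a linear filter `v0` plus `n_exc` excitatory and `n_sup` suppressive
#' quadratic components over an `L x n_electrodes` stimulus history.  Each
#' component concentrates 2-4 large-amplitude electrodes of a single polarity
#' in one lag frame (excitatory components at lag 0, suppressive at earlier
#' lags), on top of a low-amplitude Gaussian background (SD 5% of the peak)
#' that gives significance tests a true-negative set.  Component directions
#' are orthonormalized and then given distinct strengths per class
#' (geometric decay `gain_decay`) so that the quadratic form has
#' non-degenerate eigenvalues and the components are individually
#' identifiable.
#'
#' `mode = "direct"` emulates the synaptic-blockade condition, in which
#' network-mediated components disappear: the cell collapses to at most one
#' excitatory component with `v0` aligned to it, i.e. a one-dimensional
#' stimulus subspace.
#'
#' Component scale: filters are expressed in 1/uA so that the projection of
#' a white-noise stimulus (SD ~132 uA after truncation) onto a unit-strength
#' component has standard deviation `projection_sd` (default 0.5).  With the
#' default sigmoid (a = 3, b = 2, c = 1; max ~3 spikes/bin) this yields
#' roughly 0.5 spikes/bin, i.e. ~30,000 spikes per 60,000 pulses, matching
#' the spike budget of a recorded cell.
#'
#' @param n_exc,n_sup Numbers of excitatory / suppressive quadratic
#'   components.
#' @param L Number of stimulus-history lags.
#' @param n_electrodes Number of electrodes.
#' @param sigmoid Named numeric `c(a=, b=, c=)`: saturation (spikes/bin),
#'   gain, and threshold of the output sigmoid.
#' @param seed Integer seed.
#' @param mode `"network"` (full nonlinear cell) or `"direct"`
#'   (synaptic-blockade emulation).
#' @param projection_sd Target SD of the stimulus projection onto a
#'   unit-strength component, in generator units.
#' @param stimulus_sd_ua SD of the stimulus each filter will see (defaults to
#'   the truncated-Gaussian SD of the standard protocol).
#' @param v0_sd Target SD of `v0 . S`; set to 0 for a pure quadratic cell.
#' @param gain_decay Geometric decay of component strengths within a class.
#' @param orthogonalize Orthonormalize component directions (default TRUE).
#'
#' @return An object of class `ground_truth`: list with `v0`, `components`
#'   (list of `list(v, w)`), `directions` (unit vectors, columns), `w`,
#'   `sigmoid`, `L`, `n_electrodes`, `mode`, `seed`.
#' @export
make_ground_truth <- function(n_exc = 2, n_sup = 1, L = 6, n_electrodes = 20,
                              sigmoid = c(a = 3, b = 2, c = 1), seed = 1,
                              mode = c("network", "direct"),
                              projection_sd = 0.5,
                              stimulus_sd_ua = truncated_gaussian_sd(150, 300),
                              v0_sd = 0.15, gain_decay = 0.85,
                              orthogonalize = TRUE) {
  mode <- match.arg(mode)
  n_exc <- check_count(n_exc, "n_exc", min = 0)
  n_sup <- check_count(n_sup, "n_sup", min = 0)
  L <- check_count(L, "L")
  n_electrodes <- check_count(n_electrodes, "n_electrodes")
  stopifnot(all(c("a", "b", "c") %in% names(sigmoid)),
            sigmoid["a"] > 0, sigmoid["b"] > 0)
  if (mode == "direct") {
    if (n_exc > 1 || n_sup > 0) {
      n_exc <- min(n_exc, 1L)
      n_sup <- 0L
    }
  }
  d <- L * n_electrodes
  n_comp <- n_exc + n_sup
  if (n_comp > d) abort("more components requested than stimulus dimensions.")

  gt <- with_seed(derive_seed(seed, "ground_truth"), {
    raw <- matrix(0, d, 0)
    lags <- c(rep(0L, n_exc),
              if (n_sup > 0) 1L + (seq_len(n_sup) - 1L) %% max(1L, L - 1L))
    for (i in seq_len(n_comp)) {
      raw <- cbind(raw, compact_filter(L, n_electrodes, lag = lags[i]))
    }
    dirs <- if (n_comp > 0 && orthogonalize) qr.Q(qr(raw)) else
      apply(raw, 2, function(v) v / sqrt(sum(v^2)))
    dirs <- matrix(dirs, nrow = d, ncol = n_comp)
    # keep orientation close to the raw pattern
    if (n_comp > 0) {
      flip <- sign(colSums(dirs * raw))
      dirs <- sweep(dirs, 2, ifelse(flip == 0, 1, flip), `*`)
    }
    w <- c(rep(1, n_exc), rep(-1, n_sup))
    gains <- c(gain_decay^(seq_len(n_exc) - 1),
               gain_decay^(seq_len(n_sup) - 1))
    base <- projection_sd / stimulus_sd_ua
    comps <- lapply(seq_len(n_comp), function(i) {
      list(v = dirs[, i] * gains[i] * base, w = w[i])
    })

    if (v0_sd > 0) {
      if (mode == "direct" && n_comp == 1) {
        v0_dir <- dirs[, 1]
      } else if (n_comp > 0) {
        extra <- compact_filter(L, n_electrodes, lag = 0L)
        extra <- extra - dirs %*% crossprod(dirs, extra)
        extra <- extra / sqrt(sum(extra^2))
        mix <- c(0.8, rep(0, max(0, n_comp - 1)))
        v0_dir <- dirs %*% mix + sqrt(1 - sum(mix^2)) * extra
      } else {
        v0_dir <- compact_filter(L, n_electrodes, lag = 0L)
        v0_dir <- v0_dir / sqrt(sum(v0_dir^2))
      }
      v0 <- as.numeric(v0_dir) * (v0_sd / stimulus_sd_ua)
    } else {
      v0 <- numeric(d)
    }
    list(dirs = dirs, w = w, comps = comps, v0 = v0)
  })

  structure(list(
    v0 = gt$v0,
    components = gt$comps,
    directions = gt$dirs,
    w = gt$w,
    sigmoid = sigmoid[c("a", "b", "c")],
    L = L, n_electrodes = n_electrodes,
    n_exc = n_exc, n_sup = n_sup,
    mode = mode, seed = as.integer(seed)
  ), class = "ground_truth")
}

# One compact spatiotemporal pattern: 2-4 strong same-polarity electrodes in
# a single lag frame plus weak Gaussian background everywhere.
compact_filter <- function(L, n_electrodes, lag) {
  d <- L * n_electrodes
  v <- rnorm(d, 0, 0.05)
  n_sig <- sample(2:min(4, n_electrodes), 1)
  el <- sample.int(n_electrodes, n_sig)
  pol <- sample(c(-1, 1), 1)
  v[lag * n_electrodes + el] <- pol * runif(n_sig, 0.8, 1)
  matrix(v, ncol = 1)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %s-mode cell: %d excitatory + %d suppressive components, L=%d, %d electrodes\n",
    x$mode, x$n_exc, x$n_sup, x$L, x$n_electrodes
  ))
  invisible(x)
}

#' Expected spike rate of a ground-truth cell for each design row
#' @param gt A `ground_truth`.
#' @param design An `erf_design` (or plain matrix) with matching columns.
#' @return Numeric vector of Poisson means, spikes/bin.
#' @export
ground_truth_rates <- function(gt, design) {
  X <- unclass_design(design)
  if (ncol(X) != length(gt$v0)) abort("design/ground-truth dimension mismatch.")
  g <- as.numeric(X %*% gt$v0)
  for (cmp in gt$components) {
    g <- g + cmp$w * as.numeric(X %*% cmp$v)^2
  }
  sigmoid_rate(g, gt$sigmoid)
}

sigmoid_rate <- function(g, sigmoid) {
  a <- sigmoid[["a"]]; b <- sigmoid[["b"]]; cc <- sigmoid[["c"]]
  a / (1 + exp(-b * (g - cc)))
}

unclass_design <- function(design) {
  X <- design
  attributes(X) <- list(dim = dim(design))
  X
}

#' Simulate Poisson spike counts from a ground-truth cell
#'
#' The response bin for a design row is the full inter-pulse interval
#' following its lag-0 pulse; counts are independent Poisson draws with the
#' cell's expected rate.  An optional refractory dead time shrinks the
#' usable fraction of each bin.
#'
#' @inheritParams ground_truth_rates
#' @param seed Integer seed.
#' @param dead_time_ms Portion of each bin (ms) lost to, e.g., artefact
#'   blanking; scales the expected rate by the remaining fraction.  Default
#'   0 (simulation has no recording artefacts).
#' @return Integer vector of class `spike_response`, one count per design
#'   row, with attribute `total_spikes`.
#' @export
simulate_responses <- function(gt, design, seed = 1, dead_time_ms = 0) {
  rates <- ground_truth_rates(gt, design)
  if (dead_time_ms > 0) {
    f <- attr(design, "frequency_hz") %||% abort("design lacks frequency_hz.")
    rates <- rates * max(0, 1 - dead_time_ms * f / 1000)
  }
  counts <- with_seed(derive_seed(seed, "responses"),
                      rpois(length(rates), rates))
  new_spike_response(counts)
}

#' Construct a spike-response vector
#' @param counts Nonnegative integer spike counts, one per design row.
#' @return Integer vector of class `spike_response` with a `total_spikes`
#'   attribute.
#' @export
new_spike_response <- function(counts) {
  counts <- as.integer(counts)
  if (any(counts < 0)) abort("spike counts must be nonnegative.")
  structure(counts, total_spikes = sum(counts), class = "spike_response")
}

#' @export
print.spike_response <- function(x, ...) {
  cat(sprintf("<spike_response> %d bins, %d spikes (mean %.3f/bin)\n",
              length(x), attr(x, "total_spikes"),
              attr(x, "total_spikes") / length(x)))
  invisible(x)
}
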