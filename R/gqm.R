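#' Generalized Quadratic Model objects
#'
#' A `gqm` bundles a linear filter `v0`, quadratic component filters (columns
#' of `V`) with signs `w` (+1 excitatory, -1 suppressive), and a sigmoid
#' output nonlinearity `(a, b, c)`.  The generator signal is
#' `g(S) = v0 . S + sum_i w_i (v_i . S)^2` and the expected spike count is
#' `a / (1 + exp(-b * (g - c)))`.
#'
#' @param v0 Linear filter (length `L * n_electrodes`).
#' @param V Matrix of quadratic components, one column each (may have zero
#'   columns).
#' @param w Signs, +1 or -1 per component.
#' @param sigmoid Named numeric `c(a=, b=, c=)`.
#' @param L,n_electrodes,frequency_hz Stimulus-history geometry metadata.
#' @param sig_mask Optional significance masks (see
#'   [electrode_significance()]).
#' @param fit_meta Optional list of fit diagnostics.
#' @return An object of class `gqm`.
#' @export
new_gqm <- function(v0, V, w, sigmoid, L = NULL, n_electrodes = NULL,
                    frequency_hz = NULL, sig_mask = NULL, fit_meta = list()) {
  V <- as.matrix(V)
  if (length(w) != ncol(V)) abort("`w` must have one sign per component.")
  if (ncol(V) > 0 && nrow(V) != length(v0)) {
    abort("`v0` and component filters differ in length.")
  }
  if (!all(w %in% c(-1, 1))) abort("`w` entries must be +1 or -1.")
  stopifnot(all(c("a", "b", "c") %in% names(sigmoid)))
  if (sigmoid[["a"]] <= 0) abort("sigmoid saturation `a` must be positive.")
  structure(list(
    v0 = as.numeric(v0), V = V, w = as.numeric(w),
    sigmoid = sigmoid[c("a", "b", "c")],
    n_exc = sum(w > 0), n_sup = sum(w < 0),
    L = L, n_electrodes = n_electrodes, frequency_hz = frequency_hz,
    sig_mask = sig_mask, fit_meta = fit_meta
  ), class = "gqm")
}

#' Quadratic generator signal
#'
#' `g(S) = v0 . S + sum_i w_i (v_i . S)^2`, the scalar drive that the output
#' nonlinearity converts into an expected spike count.
#'
#' @param model A `gqm`.
#' @param S A stimulus-history row (vector) or matrix of rows.
#' @return Numeric vector, one generator value per stimulus row.
#' @export
generator_signal <- function(model, S) {
  S <- stim_rows(S, length(model$v0))
  g <- as.numeric(S %*% model$v0)
  if (ncol(model$V) > 0) {
    P <- S %*% model$V
    g <- g + as.numeric(P^2 %*% model$w)
  }
  g
}

stim_rows <- function(S, d) {
  if (is.null(dim(S))) {
    if (length(S) != d) abort("stimulus dimension mismatch.")
    matrix(S, 1, d)
  } else {
    S <- unclass_design(S)
    if (ncol(S) != d) abort("stimulus dimension mismatch.")
    S
  }
}

#' Expected spike count for stimuli under a fitted model
#' @inheritParams generator_signal
#' @return Numeric vector of expected spikes per bin.
#' @export
expected_response <- function(model, S) {
  sigmoid_rate(generator_signal(model, S), model$sigmoid)
}

#' @export
predict.gqm <- function(object, newdata, ...) {
  expected_response(object, newdata)
}

#' Poisson log-likelihood of observed counts given expected rates
#'
#' `sum(R * log(E) - E)`, the inhomogeneous-Poisson log-likelihood up to the
#' count-only constant `-log(R!)`.  A zero rate paired with a positive count
#' has zero likelihood: the function returns `-Inf` (documented sentinel).
#'
#' @param rates Expected counts per bin (>= 0).
#' @param counts Observed counts per bin.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
poisson_log_likelihood <- function(rates, counts) {
  rates <- as.numeric(rates); counts <- as.numeric(counts)
  if (length(rates) != length(counts)) abort("length mismatch.")
  if (any(rates < 0)) abort("negative rates.")
  if (any(rates == 0 & counts > 0)) return(-Inf)
  lg <- ifelse(counts > 0, counts * log(rates), 0)
  sum(lg - rates)
}

#' Log-likelihood of a model on a data set
#' @param model A `gqm`.
#' @param design Design matrix.
#' @param resp Aligned spike counts.
#' @return Scalar log-likelihood.
#' @export
gqm_log_likelihood <- function(model, design, resp) {
  poisson_log_likelihood(expected_response(model, design), as.numeric(resp))
}

#' Canonicalize the quadratic components of a model
#'
#' Re-expresses the quadratic form `sum_i w_i v_i v_i'` through its
#' eigendecomposition: components are replaced by orthogonal eigenvectors
#' scaled to the square root of the absolute eigenvalue, with `w_i` the
#' eigenvalue sign (excitatory first, ordered by strength).  The generator
#' signal is algebraically unchanged for every stimulus.  Numerically null
#' directions (|eigenvalue| below `tol` times the largest) are dropped, so
#' parallel components collapse into one.
#'
#' @param model A `gqm`.
#' @param tol Relative eigenvalue threshold for dropping null directions.
#' @return A `gqm` with orthogonalized, eigenvalue-scaled components.
#' @export
canonicalize_components <- function(model, tol = 1e-10) {
  if (ncol(model$V) == 0) return(model)
  M <- model$V %*% (model$w * t(model$V))
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- abs(eg$values) > tol * max(abs(eg$values), .Machine$double.eps)
  lam <- eg$values[keep]
  vec <- eg$vectors[, keep, drop = FALSE]
  # excitatory first (strongest to weakest), then suppressive by strength
  ord <- c(which(lam > 0)[order(lam[which(lam > 0)], decreasing = TRUE)],
           which(lam < 0)[order(lam[which(lam < 0)])])
  lam <- lam[ord]; vec <- vec[, ord, drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  model$V <- sweep(vec, 2, sqrt(abs(lam)), `*`)
  model$w <- sign(lam)
  model$n_exc <- sum(lam > 0)
  model$n_sup <- sum(lam < 0)
  model
}

#' Fit the sigmoid output nonlinearity to binned responses
#'
#' Sorts responses by generator-signal value, forms contiguous bins of
#' `bin_size` stimuli (the final partial bin is dropped), and least-squares
#' fits the sigmoid `a / (1 + exp(-b * (g - c)))` to the bin means.  A
#' log-exponential curve `alpha * log(1 + exp(beta * (g - gamma)))` is fit
#' alongside for comparison (it is typically poor at high generator values).
#'
#' @param g_values Generator-signal values.
#' @param counts Observed spike counts, same length.
#' @param bin_size Stimuli per bin (200 matches the reporting convention).
#' @return An object of class `sigmoid_fit`: list with `a`, `b`, `c`,
#'   `binned_curve` (tibble: `g_mean`, `response_mean`, `response_se`, `n`),
#'   `logexp` (named coefficients or NULL), `flat` (TRUE when the binned
#'   response has no spread; then the fitted curve is the constant `a`).
#' @export
fit_sigmoid_nonlinearity <- function(g_values, counts, bin_size = 200) {
  g_values <- as.numeric(g_values); counts <- as.numeric(counts)
  if (length(g_values) != length(counts)) abort("length mismatch.")
  if (length(g_values) < 2 * bin_size) {
    abort("need at least two complete bins to fit the nonlinearity.")
  }
  binned <- bin_by(g_values, counts, bin_size)
  x <- binned$g_mean; y <- binned$response_mean

  if (max(y) - min(y) < sqrt(.Machine$double.eps)) {
    return(structure(list(
      a = mean(y), b = 0, c = NA_real_, binned_curve = binned,
      logexp = NULL, flat = TRUE
    ), class = "sigmoid_fit"))
  }

  start <- list(a = max(y) * 1.05 + 1e-6,
                b = 2 / max(sd(x), 1e-8),
                c = x[which.min(abs(y - max(y) / 2))])
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ a / (1 + exp(-b * (x - c))), start = start,
      lower = c(a = 1e-8, b = 1e-8, c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    as.list(coef(m))
  }, error = function(e) {
    sse <- function(p) {
      sum((y - p[1] / (1 + exp(-p[2] * (x - p[3]))))^2)
    }
    p <- optim(unlist(start), sse, method = "L-BFGS-B",
               lower = c(1e-8, 1e-8, -Inf))$par
    list(a = p[1], b = p[2], c = p[3])
  })

  logexp <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ al * log1p(exp(be * (x - ga))),
      start = list(al = max(y) / log(2) / 2, be = 1 / max(sd(x), 1e-8),
                   ga = stats::median(x)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    stats::setNames(as.numeric(coef(m)), c("alpha", "beta", "gamma"))
  }, error = function(e) NULL)

  structure(list(
    a = fit$a, b = fit$b, c = fit$c, binned_curve = binned,
    logexp = logexp, flat = FALSE
  ), class = "sigmoid_fit")
}

bin_by <- function(g, y, bin_size) {
  ord <- order(g) # stable in R: ties keep original order
  n_bins <- floor(length(g) / bin_size)
  idx <- ord[seq_len(n_bins * bin_size)]
  grp <- rep(seq_len(n_bins), each = bin_size)
  tibble::tibble(
    g_mean = as.numeric(tapply(g[idx], grp, mean)),
    response_mean = as.numeric(tapply(y[idx], grp, mean)),
    response_se = as.numeric(tapply(y[idx], grp, function(v) {
      sd(v) / sqrt(length(v))
    })),
    response_var = as.numeric(tapply(y[idx], grp, var)),
    n = bin_size
  )
}

#' Constant-response contour of a fitted model in a component plane
#'
#' In the plane of the projections `x = v_i . S`, `y = v_j . S` (all other
#' component projections zero), the generator signal reduces to the conic
#' `g'(x, y) = k_z + k_x x + k_y y + w_i x^2 + w_j y^2`, with `k_x`, `k_y`
#' given by the projection of `v0` onto the (unit) component directions
#' divided by the component norms.  The contour at which the sigmoid output
#' equals `level` spikes/bin is an ellipse for excitatory-excitatory pairs
#' and a hyperbola for excitatory-suppressive pairs.
#'
#' @param model A canonicalized `gqm`.
#' @param i,j Component indices (distinct).
#' @param level Target expected response, strictly inside `(0, a)`.
#' @param n_points Number of x-samples used to trace the contour.
#' @return List with `coef` (named `k_z`, `k_x`, `k_y`, `w_i`, `w_j`),
#'   `g_level`, and `points` (tibble of x, y on the contour).
#' @export
response_contour <- function(model, i, j, level, n_points = 400) {
  stopifnot(i != j)
  N <- ncol(model$V)
  if (i > N || j > N) abort("component index out of range.")
  a <- model$sigmoid[["a"]]; b <- model$sigmoid[["b"]]
  cc <- model$sigmoid[["c"]]
  if (level <= 0 || level >= a) {
    abort("`level` must lie strictly inside the sigmoid output range (0, a).")
  }
  g_level <- cc - log(a / level - 1) / b

  ni <- sqrt(sum(model$V[, i]^2)); nj <- sqrt(sum(model$V[, j]^2))
  ui <- model$V[, i] / ni; uj <- model$V[, j] / nj
  k_x <- sum(model$v0 * ui) / ni
  k_y <- sum(model$v0 * uj) / nj
  k_z <- 0
  wi <- model$w[i]; wj <- model$w[j]

  # solve w_j y^2 + k_y y + (k_z + k_x x + w_i x^2 - g_level) = 0 over x
  span <- sqrt(abs(g_level) + abs(k_x) + abs(k_y) + 1) * 3
  xs <- seq(-span, span, length.out = n_points)
  pts <- purrr::map_dfr(xs, function(x) {
    cterm <- k_z + k_x * x + wi * x^2 - g_level
    disc <- k_y^2 - 4 * wj * cterm
    if (disc < 0) return(tibble::tibble(x = numeric(), y = numeric()))
    r <- (-k_y + c(1, -1) * sqrt(disc)) / (2 * wj)
    tibble::tibble(x = x, y = r)
  })
  list(coef = c(k_z = k_z, k_x = k_x, k_y = k_y, w_i = wi, w_j = wj),
       g_level = g_level, points = pts)
}

#' @export
print.gqm <- function(x, ...) {
  cat(sprintf(
    "<gqm> %d excitatory + %d suppressive components, sigmoid a=%.3g b=%.3g c=%.3g\n",
    x$n_exc, x$n_sup, x$sigmoid[["a"]], x$sigmoid[["b"]], x$sigmoid[["c"]]
  ))
  if (!is.null(x$fit_meta$loglik)) {
    cat(sprintf("  log-likelihood %.2f (%d outer iterations%s)\n",
                x$fit_meta$loglik, x$fit_meta$iterations %||% NA_integer_,
                if (isTRUE(x$fit_meta$converged)) "" else ", not converged"))
  }
  invisible(x)
}
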