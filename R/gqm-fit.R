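# Poisson maximum-likelihood fitting of the GQM.
#
# The optimizer works in a scaled stimulus space (amplitudes divided by one
# global SD) so filter coefficients are O(1), and alternates two blocks
# until the relative log-likelihood change drops below tolerance:
#   (1) sigmoid parameters (log a, log b, c) by BFGS with analytic gradients,
#   (2) all filter coefficients (v0 and components) by L-BFGS-B with
#       analytic gradients.
# Both blocks maximize the same Poisson log-likelihood, so the outer
# iteration is an ascent.

#' Fitting controls for [fit_gqm()]
#'
#' @param max_outer Maximum outer (block-alternation) iterations.
#' @param tol Relative log-likelihood improvement below which the
#'   alternation stops.
#' @param maxit_filters L-BFGS-B iteration cap per filter block.
#' @param maxit_sigmoid BFGS iteration cap per sigmoid block.
#' @return A list of control settings.
#' @export
gqm_control <- function(max_outer = 200, tol = 1e-6, maxit_filters = 100,
                        maxit_sigmoid = 50) {
  list(max_outer = max_outer, tol = tol, maxit_filters = maxit_filters,
       maxit_sigmoid = maxit_sigmoid)
}

#' Fit a Generalized Quadratic Model by Poisson maximum likelihood
#'
#' Maximizes `sum(R log E - E)` over the linear filter, the quadratic
#' component filters, and the sigmoid nonlinearity jointly, by alternating
#' analytic-gradient quasi-Newton updates of the filter block and the
#' sigmoid block.  Filters are initialized from the spike-triggered average
#' (`v0`) and the extreme STC eigenvectors (components): the top `n_exc`
#' eigenvectors seed excitatory components, the bottom `n_sup` seed
#' suppressive ones.  After convergence the components are orthogonalized
#' and scaled by the square roots of their quadratic-form eigenvalues
#' ([canonicalize_components()]).
#'
#' @param design An `erf_design` (or matrix).
#' @param resp Aligned spike counts.
#' @param n_exc,n_sup Number of excitatory / suppressive components.
#' @param init An `stc_result` used for initialization; computed from the
#'   data when `NULL`.
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @param control See [gqm_control()].
#' @param warm_start Optional `gqm` whose filters and sigmoid seed the
#'   optimizer instead of STA/STC (used by the significance bootstrap).
#' @param canonicalize Orthogonalize/rescale components after fitting.
#' @return A fitted `gqm`; `fit_meta` carries `loglik`, `loglik_path`,
#'   `iterations`, `converged` and `seed`.
#' @export
fit_gqm <- function(design, resp, n_exc = 1, n_sup = 0, init = NULL,
                    seed = 1, control = gqm_control(), warm_start = NULL,
                    canonicalize = TRUE) {
  X <- unclass_design(design)
  r <- as.numeric(resp)
  if (length(r) != nrow(X)) abort("response length does not match design rows.")
  n_exc <- check_count(n_exc, "n_exc", min = 0)
  n_sup <- check_count(n_sup, "n_sup", min = 0)
  N <- n_exc + n_sup
  d <- ncol(X)
  s <- sd(X)
  if (s == 0) abort("constant stimulus: nothing to fit.")
  Xs <- X / s
  w <- c(rep(1, n_exc), rep(-1, n_sup))

  if (!is.null(warm_start)) {
    v0s <- warm_start$v0 * s
    Vs <- warm_start$V * s
    if (ncol(Vs) != N) abort("warm start has a different component count.")
    abc <- warm_start$sigmoid
  } else {
    if (is.null(init)) init <- compute_stc(design, resp)
    if (length(init$eigenvalues) < N) {
      abort("initialization provides fewer candidate components than requested.")
    }
    # STA gives the direction of v0; cap the initial norm at 1 in scaled
    # space (the optimizer sets the magnitude)
    v0s <- init$sta * s
    nv <- sqrt(sum(v0s^2))
    if (nv > 1) v0s <- v0s / nv
    cols <- c(seq_len(n_exc),
              if (n_sup > 0) d - seq_len(n_sup) + 1L)
    Vs <- init$eigenvectors[, cols, drop = FALSE]
    abc <- NULL
  }

  fit <- gqm_engine(Xs, r, v0s, Vs, w, abc, control)

  model <- new_gqm(
    v0 = fit$v0 / s, V = fit$V / s, w = w, sigmoid = fit$abc,
    L = attr(design, "L"), n_electrodes = attr(design, "n_electrodes"),
    frequency_hz = attr(design, "frequency_hz"),
    fit_meta = list(loglik = fit$loglik, loglik_path = fit$path,
                    iterations = fit$iterations, converged = fit$converged,
                    seed = as.integer(seed))
  )
  if (canonicalize && N > 0) model <- canonicalize_components(model)
  model
}

# core alternation in scaled space
gqm_engine <- function(Xs, r, v0s, Vs, w, abc, control) {
  d <- ncol(Xs)
  N <- length(w)
  gen <- function(v0, V) {
    g <- as.numeric(Xs %*% v0)
    if (N > 0) g <- g + as.numeric((Xs %*% V)^2 %*% w)
    g
  }
  loglik <- function(g, abc) {
    E <- pmax(sigmoid_rate(g, abc), 1e-12)
    sum(r * log(E) - E)
  }

  g <- gen(v0s, Vs)
  if (is.null(abc)) abc <- init_sigmoid(g, r)
  path <- loglik(g, abc)

  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    abc <- optimize_sigmoid(g, r, abc, control$maxit_sigmoid)
    th <- optimize_filters(Xs, r, v0s, Vs, w, abc, control$maxit_filters)
    v0s <- th$v0; Vs <- th$V
    g <- gen(v0s, Vs)
    ll <- loglik(g, abc)
    path <- c(path, ll)
    rel <- (ll - path[length(path) - 1]) / max(1, abs(ll))
    if (rel < control$tol) {
      converged <- rel > -control$tol # a tiny decrease would flag trouble
      break
    }
    if (iter >= control$max_outer) break
  }
  # final sigmoid polish on the converged generator
  abc <- optimize_sigmoid(g, r, abc, control$maxit_sigmoid)
  ll <- loglik(g, abc)
  path <- c(path, ll)
  list(v0 = v0s, V = Vs, abc = abc, loglik = ll, path = path,
       iterations = iter, converged = converged)
}

init_sigmoid <- function(g, r) {
  fit <- tryCatch(
    fit_sigmoid_nonlinearity(g, r, bin_size = max(20, min(
      200, floor(length(g) / 10)))),
    error = function(e) NULL
  )
  if (!is.null(fit) && !fit$flat && fit$b > 0) {
    c(a = fit$a, b = fit$b, c = fit$c)
  } else {
    c(a = max(2 * mean(r), 0.1), b = 1 / max(sd(g), 1e-6),
      c = stats::median(g))
  }
}

optimize_sigmoid <- function(g, r, abc, maxit) {
  fn <- function(p) {
    a <- exp(p[1]); b <- exp(p[2]); cc <- p[3]
    E <- pmax(a / (1 + exp(-b * (g - cc))), 1e-12)
    -sum(r * log(E) - E)
  }
  gr <- function(p) {
    a <- exp(p[1]); b <- exp(p[2]); cc <- p[3]
    E <- a / (1 + exp(-b * (g - cc)))
    resid <- r - E
    u <- resid * (1 - E / a)
    -c(sum(resid), b * sum(u * (g - cc)), -b * sum(u))
  }
  # Box constraints keep the block in the physically meaningful regime:
  # the saturation cannot exceed a few times the largest observed count and
  # the gain is bounded relative to the generator-signal spread (a
  # razor-thin sigmoid lets the filters blow up into a degenerate optimum).
  sg <- max(sd(g), 1e-8)
  lo <- c(log(1e-4), log(1e-4 / sg), -Inf)
  hi <- c(log(5 * max(max(r), 1) + 5), log(25 / sg), Inf)
  p0 <- c(log(abc[["a"]]), log(max(abc[["b"]], 1e-8)), abc[["c"]])
  p0[1:2] <- pmin(pmax(p0[1:2], lo[1:2]), hi[1:2])
  res <- optim(p0, fn, gr, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = maxit))
  if (res$value > fn(p0)) res$par <- p0 # never accept a worse block
  c(a = exp(res$par[1]), b = exp(res$par[2]), c = res$par[3])
}

optimize_filters <- function(Xs, r, v0s, Vs, w, abc, maxit,
                             factr = 1e4) {
  d <- ncol(Xs); N <- length(w)
  a <- abc[["a"]]; b <- abc[["b"]]; cc <- abc[["c"]]
  split_par <- function(th) {
    list(v0 = th[seq_len(d)],
         V = matrix(th[-seq_len(d)], d, N))
  }
  fn <- function(th) {
    p <- split_par(th)
    g <- as.numeric(Xs %*% p$v0)
    if (N > 0) g <- g + as.numeric((Xs %*% p$V)^2 %*% w)
    E <- pmax(a / (1 + exp(-b * (g - cc))), 1e-12)
    -sum(r * log(E) - E)
  }
  gr <- function(th) {
    p <- split_par(th)
    P <- if (N > 0) Xs %*% p$V else NULL
    g <- as.numeric(Xs %*% p$v0)
    if (N > 0) g <- g + as.numeric(P^2 %*% w)
    E <- a / (1 + exp(-b * (g - cc)))
    q <- b * (r - E) * (1 - E / a) # dL/dg
    gv0 <- as.numeric(crossprod(Xs, q))
    if (N > 0) {
      gV <- 2 * sweep(crossprod(Xs, q * P), 2, w, `*`)
      -c(gv0, as.numeric(gV))
    } else {
      -gv0
    }
  }
  th0 <- c(v0s, as.numeric(Vs))
  res <- optim(th0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = factr))
  if (res$value > fn(th0)) res$par <- th0
  split_par(res$par)
}
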