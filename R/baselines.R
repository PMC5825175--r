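#' One-dimensional STC baseline model
#'
#' Projects the stimulus onto the first (largest-eigenvalue) STC component
#' and fits a double-sided sigmoid to the 200-binned mean responses along
#' the projection: independent saturating sigmoids on the positive and
#' negative half-axes sharing a common floor at zero, so the curve is
#' continuous at the origin and monotone non-decreasing in |projection| on
#' each side.  This is the linear-model baseline: a single filter, but a
#' nonlinearity that can respond to both stimulus polarities.
#'
#' @param design Design matrix.
#' @param resp Aligned spike counts.
#' @param stc Optional precomputed `stc_result`.
#' @param bin_size Stimuli per bin for the curve fit.
#' @return Object of class `stc1_baseline` with the component, the fitted
#'   half-axis parameters and the binned curve; has a `predict()` method.
#' @export
fit_stc1_baseline <- function(design, resp, stc = NULL, bin_size = 200) {
  if (is.null(stc)) stc <- compute_stc(design, resp)
  comp <- stc$eigenvectors[, 1]
  X <- unclass_design(design)
  r <- as.numeric(resp)
  proj <- as.numeric(X %*% comp)
  binned <- bin_by(proj, r, bin_size)

  near0 <- order(abs(binned$g_mean))[1:2]
  floor_k <- max(0, mean(binned$response_mean[near0]))
  fit_half <- function(sgn) {
    sel <- if (sgn > 0) binned$g_mean >= 0 else binned$g_mean < 0
    x <- abs(binned$g_mean[sel]); y <- binned$response_mean[sel]
    if (length(x) < 3) {
      return(c(A = max(0, max(y, 0) - floor_k), b = 0, c = 0))
    }
    start <- list(A = max(max(y) - floor_k, 1e-3),
                  b = 2 / max(sd(x), 1e-8),
                  c = stats::median(x))
    tryCatch({
      m <- minpack.lm::nlsLM(
        y ~ floor_k + A * (1 / (1 + exp(-b * (x - c))) -
                             1 / (1 + exp(b * c))),
        start = start, lower = c(A = 0, b = 0, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      c(A = coef(m)[["A"]], b = coef(m)[["b"]], c = coef(m)[["c"]])
    }, error = function(e) {
      sse <- function(p) {
        yy <- floor_k + p[1] * (1 / (1 + exp(-p[2] * (x - p[3]))) -
                                  1 / (1 + exp(p[2] * p[3])))
        sum((y - yy)^2)
      }
      p <- optim(unlist(start), sse, method = "L-BFGS-B",
                 lower = c(0, 0, -Inf))$par
      c(A = p[1], b = p[2], c = p[3])
    })
  }
  structure(list(
    component = comp, floor = floor_k,
    pos = fit_half(1), neg = fit_half(-1),
    binned = binned
  ), class = "stc1_baseline")
}

stc1_curve <- function(object, x) {
  half <- function(par, u) {
    object$floor + par[["A"]] *
      (1 / (1 + exp(-par[["b"]] * (u - par[["c"]]))) -
         1 / (1 + exp(par[["b"]] * par[["c"]])))
  }
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- half(object$pos, x[pos])
  out[!pos] <- half(object$neg, -x[!pos])
  pmax(out, 0)
}

#' @export
predict.stc1_baseline <- function(object, newdata, ...) {
  X <- unclass_design(newdata)
  stc1_curve(object, as.numeric(X %*% object$component))
}

#' Two-dimensional STC baseline model
#'
#' Projects the stimulus onto the two STC components whose eigenvalues
#' depart most from the shuffle null (falling back to the first and last
#' eigenvector when no null band is attached) and fits a two-dimensional
#' response surface by locally weighted linear regression (tricube weights,
#' span 0.05 of the sample) evaluated on a `grid_n` x `grid_n` grid.
#' Predictions use bilinear interpolation on the grid; queries outside the
#' grid are clamped to the nearest fitted value.
#'
#' @inheritParams fit_stc1_baseline
#' @param span Fraction of the sample entering each local fit.
#' @param grid_n Grid resolution per axis.
#' @param max_points Surface fitting subsamples to at most this many rows
#'   (deterministic thinning) to bound the cost of the local regressions.
#' @return Object of class `stc2_baseline` with the two components, the
#'   grid and fitted surface; has a `predict()` method.
#' @export
fit_stc2_baseline <- function(design, resp, stc = NULL, span = 0.05,
                              grid_n = 50, max_points = 20000) {
  if (is.null(stc)) stc <- compute_stc(design, resp)
  d <- length(stc$eigenvalues)
  if (!is.null(stc$null_hi)) {
    departure <- pmax(stc$eigenvalues - stc$null_hi,
                      stc$null_lo - stc$eigenvalues, 0)
    if (sum(departure > 0) >= 2) {
      picks <- order(departure, decreasing = TRUE)[1:2]
    } else {
      picks <- c(1L, d)
    }
  } else {
    picks <- c(1L, d)
  }
  V2 <- stc$eigenvectors[, picks, drop = FALSE]
  X <- unclass_design(design)
  r <- as.numeric(resp)
  P <- X %*% V2
  if (nrow(P) > max_points) {
    keep <- round(seq(1, nrow(P), length.out = max_points))
    P <- P[keep, , drop = FALSE]
    r <- r[keep]
  }
  surf <- lowess_surface(P[, 1], P[, 2], r, span = span, grid_n = grid_n)
  structure(list(components = V2, picks = picks, surface = surf),
            class = "stc2_baseline")
}

# Locally weighted linear regression surface on a regular grid.
lowess_surface <- function(x, y, z, span = 0.05, grid_n = 50) {
  n <- length(x)
  k <- max(10L, ceiling(span * n))
  gx <- seq(min(x), max(x), length.out = grid_n)
  gy <- seq(min(y), max(y), length.out = grid_n)
  grid <- as.matrix(expand.grid(gx = gx, gy = gy))
  M <- cbind(1, x, y, x^2, x * y, y^2, z, x * z, y * z)
  fitted <- rep(NA_real_, nrow(grid))
  chunk <- 500L
  for (start in seq(1, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    G <- grid[idx, , drop = FALSE]
    D2 <- outer(G[, 1]^2 + G[, 2]^2, x^2 + y^2, `+`) -
      2 * G %*% rbind(x, y)
    D2[D2 < 0] <- 0
    for (m in seq_along(idx)) {
      d2 <- D2[m, ]
      h2 <- sort(d2, partial = k)[k]
      if (h2 <= 0) h2 <- max(d2[d2 > 0], .Machine$double.eps)
      w <- (1 - pmin(d2 / h2, 1)^1.5)^3 # tricube in distance: (1-(d/h)^3)^3
      S <- crossprod(w, M)[1, ]
      fitted[idx[m]] <- local_linear_value(S, G[m, 1], G[m, 2])
    }
  }
  # clamp any unfit cells to the nearest fitted neighbour
  if (anyNA(fitted)) {
    ok <- which(!is.na(fitted))
    for (m in which(is.na(fitted))) {
      d2 <- (grid[ok, 1] - grid[m, 1])^2 + (grid[ok, 2] - grid[m, 2])^2
      fitted[m] <- fitted[ok[which.min(d2)]]
    }
  }
  list(gx = gx, gy = gy,
       z = matrix(pmax(fitted, 0), grid_n, grid_n)) # z[i,j] at (gx[i], gy[j])
}

# Solve the weighted local-linear normal equations from raw moments and
# return the fitted value at (gx, gy).
local_linear_value <- function(S, gx, gy) {
  Sw <- S[1]; Sx <- S[2]; Sy <- S[3]; Sxx <- S[4]; Sxy <- S[5]; Syy <- S[6]
  Sz <- S[7]; Sxz <- S[8]; Syz <- S[9]
  if (Sw <= 0) return(NA_real_)
  # moments about the grid point
  dx <- Sx - gx * Sw; dy <- Sy - gy * Sw
  dxx <- Sxx - 2 * gx * Sx + gx^2 * Sw
  dyy <- Syy - 2 * gy * Sy + gy^2 * Sw
  dxy <- Sxy - gx * Sy - gy * Sx + gx * gy * Sw
  dz <- Sz; dxz <- Sxz - gx * Sz; dyz <- Syz - gy * Sz
  A <- matrix(c(Sw, dx, dy,
                dx, dxx, dxy,
                dy, dxy, dyy), 3, 3)
  b <- c(dz, dxz, dyz)
  beta <- tryCatch(solve(A, b), error = function(e) c(dz / Sw, 0, 0))
  beta[1]
}

#' @export
predict.stc2_baseline <- function(object, newdata, ...) {
  X <- unclass_design(newdata)
  P <- X %*% object$components
  s <- object$surface
  interp_bilinear(s$gx, s$gy, s$z, P[, 1], P[, 2])
}

interp_bilinear <- function(gx, gy, z, qx, qy) {
  qx <- pmin(pmax(qx, gx[1]), gx[length(gx)])
  qy <- pmin(pmax(qy, gy[1]), gy[length(gy)])
  ix <- pmin(findInterval(qx, gx), length(gx) - 1L)
  iy <- pmin(findInterval(qy, gy), length(gy) - 1L)
  tx <- (qx - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (qy - gy[iy]) / (gy[iy + 1L] - gy[iy])
  z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    z[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    z[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    z[cbind(ix + 1L, iy + 1L)] * tx * ty
}
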