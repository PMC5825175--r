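#' Select the number of excitatory and suppressive components
#'
#' Greedy grid search over model order, mirroring the incremental procedure
#' used to pick the stimulus-subspace dimensionality: starting from the
#' linear-filter-only model (0, 0), each step tries adding one excitatory or
#' one suppressive component (initialized from the next unused STC
#' eigenvector and warm-started from the current fit), keeps whichever
#' improves held-out performance most, and stops when the best improvement
#' falls below `tol` (ties broken toward fewer components, excitatory before
#' suppressive).  Held-out performance uses a contiguous k-fold split with
#' the last `n_eval_folds` folds as validation.
#'
#' Two selection metrics are available.  The default, `"loglik"`, is the
#' held-out Poisson log-likelihood per response bin: it is the natural
#' predictive criterion for a Poisson spiking model and cleanly penalizes
#' spurious components.  `"r2"` is the held-out binned-R-squared variant
#' (`tol` then defaults to 0.01); it saturates once the dominant component
#' is in the model and can be insensitive to genuine suppressive structure,
#' so it is kept for comparison rather than as the default.
#'
#' @inheritParams fit_gqm
#' @param max_exc,max_sup Search caps.
#' @param k Folds for the contiguous split.
#' @param n_eval_folds How many validation folds to use.
#' @param metric `"loglik"` (held-out log-likelihood per bin) or `"r2"`
#'   (held-out binned R-squared).
#' @param tol Minimum held-out improvement to accept a component (per bin
#'   for `"loglik"`); defaults to 0.002 for `"loglik"` and 0.01 for `"r2"`.
#' @param bin_size Stimuli per validation bin (for `"r2"`).
#' @param control Fitting controls for the candidate fits (kept short: the
#'   search only needs the relative ranking of candidate orders; the
#'   selected order is refit at [gqm_control()] defaults).
#' @param max_train_rows Candidate fits use at most this many (earliest)
#'   training rows; the final refit uses all of them.
#' @return List with `n_exc`, `n_sup`, `score` (held-out metric of the
#'   selected order), `model` (the selected fit, canonicalized), `r2`
#'   (held-out binned R-squared of the selected fit) and `path` (tibble of
#'   the search trajectory).
#' @export
select_model_order <- function(design, resp, max_exc = 3, max_sup = 3,
                               seed = 1, k = 5, n_eval_folds = 1,
                               metric = c("loglik", "r2"), tol = NULL,
                               bin_size = 200,
                               control = gqm_control(max_outer = 3,
                                                     maxit_filters = 60),
                               max_train_rows = 25000) {
  metric <- match.arg(metric)
  tol <- tol %||% if (metric == "loglik") 0.002 else 0.01
  r <- as.numeric(resp)
  folds <- crossval_split(nrow(design), k = k)
  eval_folds <- seq.int(k - n_eval_folds + 1L, k)
  test_idx <- sort(unlist(folds[eval_folds]))
  train_idx <- setdiff(seq_len(nrow(design)), test_idx)
  Xtr <- subset_design(design, train_idx)
  Xte <- subset_design(design, test_idx)
  rtr <- r[train_idx]; rte <- r[test_idx]
  sub_idx <- seq_len(min(length(rtr), max_train_rows))
  Xsub <- subset_design(Xtr, sub_idx)
  rsub <- rtr[sub_idx]
  init <- compute_stc(Xsub, rsub)
  s <- sd(unclass_design(Xsub))
  d <- ncol(design)

  score_of <- function(model) {
    if (metric == "loglik") {
      poisson_log_likelihood(pmax(predict(model, Xte), 1e-12), rte) /
        length(rte)
    } else {
      r2 <- coefficient_of_determination(
        binned_prediction_curve(predict(model, Xte), rte, bin_size))
      if (is.na(r2)) -Inf else r2
    }
  }
  fit_candidate <- function(ne, ns, warm) {
    if (is.null(warm)) {
      fit_gqm(Xsub, rsub, n_exc = ne, n_sup = ns, init = init, seed = seed,
              control = control, canonicalize = FALSE)
    } else {
      # warm start: current filters plus one fresh STC-seeded component,
      # columns ordered excitatory-first as fit_gqm expects
      new_col <- if (ne > warm$n_exc) {
        init$eigenvectors[, ne, drop = FALSE] / s
      } else {
        init$eigenvectors[, d - ns + 1L, drop = FALSE] / s
      }
      exc_cols <- which(warm$w > 0)
      sup_cols <- which(warm$w < 0)
      V <- if (ne > warm$n_exc) {
        cbind(warm$V[, exc_cols, drop = FALSE], new_col,
              warm$V[, sup_cols, drop = FALSE])
      } else {
        cbind(warm$V[, exc_cols, drop = FALSE],
              warm$V[, sup_cols, drop = FALSE], new_col)
      }
      ws <- new_gqm(v0 = warm$v0, V = V,
                    w = c(rep(1, ne), rep(-1, ns)),
                    sigmoid = warm$sigmoid)
      fit_gqm(Xsub, rsub, n_exc = ne, n_sup = ns, warm_start = ws,
              seed = seed, control = control, canonicalize = FALSE)
    }
  }

  cur_fit <- fit_candidate(0, 0, NULL)
  cur_score <- score_of(cur_fit)
  path <- list(tibble::tibble(n_exc = 0L, n_sup = 0L, score = cur_score,
                              accepted = TRUE))
  repeat {
    cand <- list()
    if (cur_fit$n_exc < max_exc) {
      cand$exc <- c(cur_fit$n_exc + 1L, cur_fit$n_sup)
    }
    if (cur_fit$n_sup < max_sup) {
      cand$sup <- c(cur_fit$n_exc, cur_fit$n_sup + 1L)
    }
    if (length(cand) == 0) break
    fits <- lapply(cand, function(cs) fit_candidate(cs[1], cs[2], cur_fit))
    scores <- vapply(fits, score_of, numeric(1))
    best <- which.max(scores) # first max: excitatory wins exact ties
    for (j in seq_along(cand)) {
      path[[length(path) + 1]] <- tibble::tibble(
        n_exc = cand[[j]][1], n_sup = cand[[j]][2], score = scores[j],
        accepted = j == best && scores[best] - cur_score >= tol
      )
    }
    if (scores[best] - cur_score < tol) break
    cur_fit <- fits[[best]]
    cur_score <- scores[best]
  }
  # refit the selected order on the full training portion
  model <- fit_gqm(Xtr, rtr, n_exc = cur_fit$n_exc, n_sup = cur_fit$n_sup,
                   init = init, seed = seed)
  r2 <- coefficient_of_determination(
    binned_prediction_curve(predict(model, Xte), rte, bin_size))
  list(n_exc = cur_fit$n_exc, n_sup = cur_fit$n_sup, score = cur_score,
       r2 = r2, model = model, path = dplyr::bind_rows(path))
}

#' Bootstrap significance of electrode contributions
#'
#' Builds a null distribution for every filter coefficient by circularly
#' time-shifting the response vector (offset at least `L` rows, which
#' destroys stimulus-response alignment while preserving response
#' autocorrelation) and re-estimating the model from a warm start at the
#' fitted parameters.  A coefficient is significant when its absolute fitted
#' value exceeds `threshold_sd` null standard deviations (default 2), or,
#' with `method = "ci"`, when it falls outside the central
#' `1 - alpha` null quantile band.
#'
#' @param model A fitted `gqm`.
#' @param design,resp The data the model was fitted on.
#' @param n_boot Number of time-shifted re-estimates (values below 50 give
#'   unstable null SDs and trigger a warning).
#' @param threshold_sd Significance threshold in null SDs.
#' @param seed Integer seed.
#' @param method `"sd"` (2-SD rule) or `"ci"` (quantile band).
#' @param alpha Band level for `method = "ci"`.
#' @param refit_maxit L-BFGS-B iteration cap per null re-estimate; the
#'   re-estimates use a looser convergence factor (`factr = 1e7`) than the
#'   main fit, which reaches statistical convergence quickly from the warm
#'   start.
#' @return The model with `sig_mask` set: list with logical `v0` (length d)
#'   and `components` (d x N matrix), plus null SDs and settings in
#'   `sig_meta`.
#' @export
electrode_significance <- function(model, design, resp, n_boot = 1000,
                                   threshold_sd = 2, seed = 1,
                                   method = c("sd", "ci"), alpha = 0.05,
                                   refit_maxit = 100) {
  method <- match.arg(method)
  n_boot <- check_count(n_boot, "n_boot")
  if (n_boot < 50) warn("n_boot < 50: null SDs will be unstable.")
  X <- unclass_design(design)
  r <- as.numeric(resp)
  L <- attr(design, "L") %||% model$L %||% 1L
  n <- nrow(X)
  d <- ncol(X); N <- ncol(model$V)
  s <- sd(X)
  Xs <- X / s
  v0s <- model$v0 * s
  Vs <- model$V * s

  draws <- with_seed(derive_seed(seed, "electrode_sig"), {
    shifts <- sample.int(n - 2L * L + 1L, n_boot, replace = TRUE) + L - 1L
    vapply(shifts, function(sft) {
      rs <- circular_shift(r, sft)
      th <- optimize_filters(Xs, rs, v0s, Vs, model$w, model$sigmoid,
                             refit_maxit, factr = 1e7)
      c(th$v0, as.numeric(th$V)) / s
    }, numeric(d * (N + 1)))
  })

  null_sd <- apply(draws, 1, sd)
  co <- c(model$v0, as.numeric(model$V))
  if (method == "sd") {
    sig <- abs(co) > threshold_sd * null_sd
  } else {
    lo <- apply(draws, 1, quantile, probs = alpha / 2, names = FALSE)
    hi <- apply(draws, 1, quantile, probs = 1 - alpha / 2, names = FALSE)
    sig <- co < lo | co > hi
  }
  # coefficients on constant (unidentifiable) stimulus columns are never
  # significant
  const_cols <- which(apply(X, 2, function(col) max(col) == min(col)))
  if (length(const_cols) > 0) {
    for (k in seq_len(N + 1)) sig[(k - 1) * d + const_cols] <- FALSE
  }

  model$sig_mask <- list(
    v0 = sig[seq_len(d)],
    components = if (N > 0) matrix(sig[-seq_len(d)], d, N) else
      matrix(FALSE, d, 0)
  )
  model$sig_meta <- list(
    null_sd_v0 = null_sd[seq_len(d)],
    null_sd_components = if (N > 0) matrix(null_sd[-seq_len(d)], d, N) else
      matrix(NA_real_, d, 0),
    n_boot = n_boot, threshold_sd = threshold_sd, method = method,
    alpha = alpha, seed = as.integer(seed)
  )
  model
}
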