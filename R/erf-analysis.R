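#' Stimulus-integration time from the significance mask
#'
#' The integration time of a cell is the longest stimulus lag at which any
#' electrode still significantly influences the response, reported
#' separately for excitatory and suppressive components.  Lags are converted
#' to milliseconds via the inter-pulse interval, so the result is always a
#' multiple of `1000 / frequency_hz` (lag 0 gives 0 ms).  Uses the bootstrap
#' significance mask, not raw amplitudes.
#'
#' @param model A `gqm` with `sig_mask` set (see
#'   [electrode_significance()]).
#' @param frequency_hz Pulse rate; defaults to the model's.
#' @return Tibble with one row per class (`excitatory`, `suppressive`):
#'   `integration_ms` (0 when the class has no significant entries) and
#'   `any_significant`.
#' @export
integration_time <- function(model, frequency_hz = NULL) {
  f <- frequency_hz %||% model$frequency_hz
  if (is.null(f)) abort("`frequency_hz` not supplied and not on the model.")
  if (is.null(model$sig_mask)) {
    abort("model has no significance mask; run electrode_significance() first.")
  }
  ne <- model$n_electrodes %||% abort("model lacks electrode-count metadata.")
  L <- model$L %||% (length(model$v0) / ne)
  per_class <- function(w_sign) {
    cols <- which(model$w == w_sign)
    mask <- model$sig_mask$components[, cols, drop = FALSE]
    if (length(mask) == 0 || !any(mask)) {
      return(c(ms = 0, any = 0))
    }
    lags <- (which(mask, arr.ind = TRUE)[, 1] - 1) %/% ne
    c(ms = max(lags) * 1000 / f, any = 1)
  }
  ex <- per_class(1); su <- per_class(-1)
  tibble::tibble(
    class = c("excitatory", "suppressive"),
    integration_ms = unname(c(ex["ms"], su["ms"])),
    any_significant = unname(c(ex["any"], su["any"])) == 1
  )
}

#' Electrical receptive-field size
#'
#' Amplitude-weighted mean distance between the significant electrodes of a
#' component and the recording location:
#' `sum(|v_e| * dist_e) / sum(|v_e|)` over significant (lag, electrode)
#' entries, in mm.  Invariant to global rescaling of the component.
#'
#' @param component Numeric filter vector (length `L * n_electrodes`).
#' @param sig_mask Logical vector of the same length marking significant
#'   entries.
#' @param array The `electrode_array` (carries the recording location).
#' @return Distance in mm; `NA` with a warning when nothing is significant.
#' @export
erf_size <- function(component, sig_mask, array) {
  ne <- nrow(array)
  if (length(component) %% ne != 0) {
    abort("component length is not a multiple of the electrode count.")
  }
  if (length(sig_mask) != length(component)) abort("mask length mismatch.")
  if (!any(sig_mask)) {
    warn("no significant electrodes; ERF size undefined.")
    return(NA_real_)
  }
  dists <- electrode_distances(array)
  el <- (which(sig_mask) - 1) %% ne + 1
  wts <- abs(component[sig_mask])
  sum(wts * dists[el]) / sum(wts)
}

#' Polarity preference along an ERF component
#'
#' Projects the stimuli onto the component, bins the responses along the
#' projection separately for positive (anodic-first) and negative
#' (cathodic-first) projections, and reports the maximum mean response on
#' each half-axis normalized by the larger of the two (so
#' `max(anodic, cathodic) = 1`).  The statistic is only meaningful for
#' components whose significant electrodes share one polarity; mixed-sign
#' components are flagged non-applicable.
#'
#' @param component Numeric filter vector.
#' @param design Design matrix.
#' @param resp Aligned spike counts.
#' @param sig_mask Optional logical vector; when supplied, polarity
#'   uniformity is checked on the significant entries.
#' @param bin_size Stimuli per bin along the projection.
#' @return List with `anodic_sat`, `cathodic_sat` (in `[0, 1]`) and
#'   `applicable`.
#' @export
polarity_preference <- function(component, design, resp, sig_mask = NULL,
                                bin_size = 200) {
  X <- unclass_design(design)
  r <- as.numeric(resp)
  if (!is.null(sig_mask)) {
    signs <- sign(component[sig_mask & component != 0])
    if (length(signs) == 0 || length(unique(signs)) > 1) {
      return(list(anodic_sat = NA_real_, cathodic_sat = NA_real_,
                  applicable = FALSE))
    }
    # orient so significant electrodes are positive: positive projection
    # then means anodic-first drive of the ERF
    if (signs[1] < 0) component <- -component
  }
  proj <- as.numeric(X %*% component)
  pos <- proj > 0; neg <- proj < 0
  if (sum(pos) < bin_size || sum(neg) < bin_size) {
    abort("too few samples on one projection half-axis.")
  }
  max_mean <- function(idx) {
    b <- bin_by(proj[idx], r[idx], bin_size)
    max(b$response_mean)
  }
  an <- max_mean(pos); ca <- max_mean(neg)
  top <- max(an, ca)
  list(anodic_sat = an / top, cathodic_sat = ca / top, applicable = TRUE)
}

#' Reconstruct the linear filter from the quadratic subspace
#'
#' Tests whether `v0` lies in the span of the quadratic components: with
#' orthonormal components in the columns of `V`, the weights are
#' `b = V' v0`, the reconstruction is `u0 = V b`, and the cosine similarity
#' between `v0` and its reconstruction equals `||u0|| / ||v0||` (1 when
#' `v0` is fully contained in the subspace, 0 when orthogonal to it).
#'
#' @param v0 Linear filter vector.
#' @param components Matrix with orthogonal component columns (normalized
#'   internally), or a list of component vectors.
#' @return List with `b_weights`, `u0`, `similarity`; `similarity` is `NA`
#'   (with a warning) for a zero `v0`.
#' @export
linear_component_similarity <- function(v0, components) {
  V <- if (is.list(components)) {
    do.call(cbind, lapply(components, function(cmp) {
      if (is.list(cmp)) cmp$v else cmp
    }))
  } else {
    as.matrix(components)
  }
  norms <- sqrt(colSums(V^2))
  if (any(norms == 0)) abort("zero-norm component.")
  V <- sweep(V, 2, norms, `/`)
  gram <- crossprod(V)
  if (max(abs(gram - diag(ncol(V)))) > 1e-6) {
    abort("components are not orthogonal; canonicalize the model first.")
  }
  nv0 <- sqrt(sum(v0^2))
  if (nv0 == 0) {
    warn("zero linear filter; similarity undefined.")
    return(list(b_weights = rep(NA_real_, ncol(V)), u0 = v0,
                similarity = NA_real_))
  }
  b <- as.numeric(crossprod(V, v0))
  u0 <- as.numeric(V %*% b)
  list(b_weights = b, u0 = u0, similarity = sqrt(sum(u0^2)) / nv0)
}

#' Summarize the electrical receptive field of a fitted cell
#'
#' Convenience wrapper assembling the post-fit characterization: per-class
#' integration times, per-component ERF sizes and polarity preferences, and
#' the linear-component reconstruction similarity.
#'
#' @param model A canonicalized `gqm` with `sig_mask` set.
#' @param array The `electrode_array`.
#' @param design,resp The data (used for polarity preferences).
#' @return List of class `erf_summary` with elements `integration`,
#'   `components` (tibble: class, erf_size_mm, anodic_sat, cathodic_sat,
#'   polarity_applicable), `similarity`, `b_weights`.
#' @export
erf_summary <- function(model, array, design, resp) {
  integ <- integration_time(model)
  N <- ncol(model$V)
  comp_rows <- purrr::map_dfr(seq_len(N), function(i) {
    mask <- model$sig_mask$components[, i]
    size <- if (any(mask)) erf_size(model$V[, i], mask, array) else NA_real_
    pol <- tryCatch(
      polarity_preference(model$V[, i], design, resp, sig_mask = mask),
      error = function(e) list(anodic_sat = NA_real_,
                               cathodic_sat = NA_real_, applicable = FALSE)
    )
    tibble::tibble(
      component = i,
      class = if (model$w[i] > 0) "excitatory" else "suppressive",
      erf_size_mm = size,
      anodic_sat = pol$anodic_sat, cathodic_sat = pol$cathodic_sat,
      polarity_applicable = pol$applicable
    )
  })
  sim <- if (N > 0 && sqrt(sum(model$v0^2)) > 0) {
    linear_component_similarity(model$v0, model$V)
  } else {
    list(b_weights = numeric(), u0 = model$v0, similarity = NA_real_)
  }
  structure(list(
    integration = integ,
    components = comp_rows,
    similarity = sim$similarity,
    b_weights = sim$b_weights
  ), class = "erf_summary")
}
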