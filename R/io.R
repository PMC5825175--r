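# Plain-text persistence: pulse trains and responses as commented CSV,
# models as versioned JSON.  Text formats keep artifacts diffable; this
# domain has no entrenched binary container for stimulation records.

#' Write / read a stimulus train as commented CSV
#'
#' One row per pulse, columns `e01..eNN` in uA; metadata (`frequency_hz`,
#' `sigma_ua`, `limit_ua`, `seed`) stored in `#`-prefixed header lines.
#'
#' @param train A `stim_train`.
#' @param path File path.
#' @return `write_train` returns `path` invisibly; `read_train` returns a
#'   `stim_train`.
#' @export
write_train <- function(train, path) {
  meta <- c(
    sprintf("# frequency_hz: %.10g", attr(train, "frequency_hz")),
    sprintf("# sigma_ua: %.10g", attr(train, "sigma_ua") %||% NA),
    sprintf("# limit_ua: %.10g", attr(train, "limit_ua") %||% NA),
    sprintf("# seed: %d", as.integer(attr(train, "seed") %||% NA))
  )
  writeLines(meta, path)
  readr::write_csv(as.data.frame(unclass(train)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_train
#' @export
read_train <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) abort(sprintf("empty input file: %s", path))
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_meta(meta_lines)
  if (is.na(meta[["frequency_hz"]])) {
    abort("missing `frequency_hz` metadata in train file.")
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2) abort(sprintf("no data rows in: %s", path))
  df <- parse_csv_strict(body, path, offset = length(meta_lines))
  tr <- new_stim_train(as.matrix(df), frequency_hz = meta[["frequency_hz"]],
                       sigma_ua = meta[["sigma_ua"]],
                       limit_ua = meta[["limit_ua"]],
                       seed = as.integer(meta[["seed"]]))
  tr
}

parse_meta <- function(meta_lines) {
  get1 <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), meta_lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    suppressWarnings(as.numeric(sub(".*:\\s*", "", hit[1])))
  }
  c(frequency_hz = get1("frequency_hz"), sigma_ua = get1("sigma_ua"),
    limit_ua = get1("limit_ua"), seed = get1("seed"))
}

# Strict CSV body parser that reports 1-based file line numbers on failure.
parse_csv_strict <- function(body, path, offset = 0) {
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  n_col <- length(header)
  rows <- lapply(seq.int(2, length(body)), function(i) {
    cells <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    line_no <- i + offset
    if (length(cells) != n_col) {
      abort(sprintf("%s: line %d has %d columns, expected %d.",
                    path, line_no, length(cells), n_col))
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      abort(sprintf("%s: non-numeric cell at line %d.", path, line_no))
    }
    vals
  })
  out <- do.call(rbind, rows)
  colnames(out) <- header
  as.data.frame(out)
}

#' Write / read spike responses as single-column commented CSV
#' @param resp A `spike_response` (or integer vector).
#' @param path File path.
#' @return `write_responses` returns `path` invisibly; `read_responses`
#'   returns a `spike_response`.
#' @export
write_responses <- function(resp, path) {
  writeLines(c(sprintf("# total_spikes: %d", sum(as.numeric(resp))),
               "count",
               format(as.integer(resp), trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) abort(sprintf("empty input file: %s", path))
  offset <- sum(grepl("^#", lines))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2) abort(sprintf("no data rows in: %s", path))
  vals <- suppressWarnings(as.numeric(body[-1]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1] + 1 + offset
    abort(sprintf("%s: non-numeric cell at line %d.", path, bad))
  }
  new_spike_response(vals)
}

#' Serialize / restore a fitted model as versioned JSON
#'
#' Filters are stored as flat arrays with their `(L, n_electrodes)` shape,
#' along with the sigmoid, signs, significance masks and fit provenance
#' (seed, log-likelihood, input hashes when supplied).
#'
#' @param model A `gqm`.
#' @param path File path.
#' @param data_hash Optional content hash of the fitted data to embed.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns a `gqm`.
#' @export
write_model_json <- function(model, path, data_hash = NULL) {
  payload <- list(
    format = "erfield-gqm", version = 1L,
    shape = list(L = model$L, n_electrodes = model$n_electrodes,
                 frequency_hz = model$frequency_hz),
    v0 = model$v0,
    components = asplit_cols(model$V),
    w = model$w,
    sigmoid = as.list(model$sigmoid),
    sig_mask = if (!is.null(model$sig_mask)) {
      list(v0 = model$sig_mask$v0,
           components = asplit_cols(model$sig_mask$components))
    },
    fit_meta = model$fit_meta[c("loglik", "iterations", "converged", "seed")],
    data_hash = data_hash
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

asplit_cols <- function(M) {
  lapply(seq_len(ncol(M)), function(j) M[, j])
}

# jsonlite may return a list of columns or (simplified) a rows-matrix
cols_from_json <- function(x, d) {
  if (is.null(x) || length(x) == 0) return(matrix(0, d, 0))
  if (is.matrix(x)) return(t(x))
  do.call(cbind, lapply(x, as.numeric))
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "erfield-gqm")) abort("not an erfield model file.")
  V <- cols_from_json(p$components, length(p$v0))
  mask <- if (!is.null(p$sig_mask)) {
    list(v0 = as.logical(p$sig_mask$v0),
         components = matrix(as.logical(
           cols_from_json(p$sig_mask$components, length(p$v0))),
           length(p$v0)))
  }
  new_gqm(
    v0 = p$v0, V = V, w = p$w,
    sigmoid = unlist(p$sigmoid)[c("a", "b", "c")],
    L = p$shape$L, n_electrodes = p$shape$n_electrodes,
    frequency_hz = p$shape$frequency_hz,
    sig_mask = mask,
    fit_meta = p$fit_meta
  )
}
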