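# Internal helpers shared across modules.

# Deterministic fan-out of one master seed into per-task streams.  Keeps the
# derived seed strictly inside the 32-bit signed range R uses for set.seed().
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- (abs(as.numeric(seed)) %% 2147483647)
  k <- sum(utf8ToInt(as.character(key))) * 7919
  as.integer((s * 69621 + k) %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a whole number >= %s.", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive number.", name))
  }
  as.numeric(x)
}

# Cosine of the angle between two vectors.
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}
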