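`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic per-key pseudo-random uniforms, independent of the global RNG.
# Polynomial string hash over a Mersenne-prime modulus followed by one
# Lehmer step; good enough to decorrelate neighbouring doc ids for mock
# scorers, not a cryptographic hash.
.hash_string <- function(s, seed = 0L) {
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (i in utf8ToInt(s)) h <- (h * 31 + i) %% m
  h
}

#' Deterministic uniform draws keyed by strings
#'
#' Maps each key to a value in `[0, 1)` that depends only on the key, the
#' `salt`, and the `seed`. Used by the mock scorers so that repeated calls
#' with the same inputs give identical results without touching the global
#' random number generator state.
#'
#' @param keys character vector of keys.
#' @param seed integer seed.
#' @param salt extra string mixed into the hash so independent draws can be
#'   taken for the same key.
#' @return numeric vector in `[0, 1)`, one value per key.
#' @keywords internal
unit_hash <- function(keys, seed = 0L, salt = "") {
  m <- 2147483647
  vapply(keys, function(k) {
    h <- .hash_string(paste(salt, k, sep = "\r"), seed)
    h <- (h * 48271) %% m
    h <- (h * 48271) %% m
    h / m
  }, numeric(1), USE.NAMES = FALSE)
}

# Canonical topic ordering used by all writers: numeric when every id parses
# as a number (the TREC convention), lexicographic otherwise.
.order_topic_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (anyNA(num)) order(ids) else order(num, ids)
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}
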