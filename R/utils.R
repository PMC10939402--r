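# Internal helpers: classed conditions and seed plumbing.

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("hardivine_schema_error", "hardivine_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("hardivine_validation_error", "hardivine_error")))
}

stop_compute <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("hardivine_compute_error", "hardivine_error")))
}

# Derive a child seed from a master seed and a stream label; stays < 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- rlang::hash(key)
  # fold the first 8 hex digits into a positive 31-bit integer
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Look up a canonical column name in a user dialect map, defaulting to itself.
dialect_col <- function(dialect, canon) {
  if (canon %in% names(dialect)) unname(dialect[[canon]]) else canon
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
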