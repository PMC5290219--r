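# Internal helpers shared across modules.

# Round half away from zero (round-half-up for positive x). Used for the
# misleading-participant count and the train-set size, where base R's
# banker's rounding would make n = 2, fraction = 0.5 ambiguous.
round_half_up <- function(x) floor(x + 0.5)

# Validate a half-open sample interval [start, end) against a series length.
check_interval <- function(interval, n, what = "interval") {
  if (length(interval) != 2L || any(!is.finite(interval))) {
    stop(sprintf("%s must be a length-2 numeric [start, end)", what), call. = FALSE)
  }
  start <- interval[[1L]]; end <- interval[[2L]]
  if (start < 0 || end > n || start >= end) {
    stop(sprintf("%s [%s, %s) out of range for series of length %d",
                 what, format(start), format(end), n), call. = FALSE)
  }
  invisible(interval)
}

# Slice a series by a 0-based half-open interval.
slice_interval <- function(x, interval) {
  x[(interval[[1L]] + 1L):interval[[2L]]]
}

# Euclidean norms of the rows of a matrix.
row_norms <- function(X) sqrt(rowSums(X^2))

# Derive k reproducible substream seeds from one master seed without
# disturbing the caller's RNG state.
derive_seeds <- function(master_seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
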