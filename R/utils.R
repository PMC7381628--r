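# Internal helpers shared across modules.

# Deterministically derive `n` child seeds from a master seed, keeping each
# below .Machine$integer.max so they remain valid 32-bit seeds.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Runs of TRUE in a logical vector -> tibble(start, end, length) (indices).
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values],
                 length = r$lengths[r$values])
}
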