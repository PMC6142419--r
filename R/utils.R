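# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a base seed and an offset
#'
#' Simple multiplicative mix kept below 2^31 so it is always a valid
#' `set.seed()` argument. Used so that every assay, replicate and Monte Carlo
#' repetition gets its own reproducible stream from one top-level seed.
#'
#' @param seed integer base seed.
#' @param offset integer offset distinguishing the consumer.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 8191) %% 2147483587)
}

# stop() with sprintf formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
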