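# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with a sequence of integer keys (repeat index, fold
#' index, stage tag, ...) into a new seed, so that every stochastic unit of a
#' nested run draws from its own stream while remaining fully determined by
#' the master seed. The recurrence is a Lehmer-style multiplicative hash kept
#' below 2^31 - 1 so the result is always a valid \code{set.seed()} argument.
#'
#' @param seed Integer master seed.
#' @param ... Integer keys identifying the stochastic unit.
#' @return A single integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.double(seed) %% 2147483647
  # 69069 * s stays below 2^53, so the double arithmetic is exact
  for (k in c(keys, 0)) {
    s <- (69069 * s + as.double(k) + 1) %% 2147483647
  }
  as.integer(s + 1)
}

# round-half-up at `digits` decimals; base round() uses banker's rounding,
# while study-style percentage tables round 64.25 -> 64.3
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_ganest <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

# uniform draw from a candidate vector that is safe for length 1
# (sample(5L, 1) would draw from 1:5, not from {5})
sample_one <- function(candidates) {
  candidates[sample.int(length(candidates), 1L)]
}
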