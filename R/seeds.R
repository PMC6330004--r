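#' Derive a reproducible child seed from a master seed
#'
#' All stochastic steps in the package draw their own seed from a single
#' master seed through this fixed arithmetic scheme, so that any replicate
#' (or any permutation within a replicate) can be re-run in isolation
#' without replaying the whole stream.
#'
#' @param seed Master seed (single integer).
#' @param ... One or more non-negative integer keys identifying the
#'   sub-stream (e.g. replicate index, permutation index).  Keys are folded
#'   in order.
#' @return A single integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic stays < 2^53
  s <- as.numeric(seed) %% m
  for (k in as.numeric(keys)) {
    s <- (s * 48271 + k * 1299709 + 12345) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}
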