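#' Derive a child seed from a root seed
#'
#' Every stochastic component (medium draw, glyph, noise, drift step, weight
#' initialization) derives its own seed from a single root seed and a stage
#' counter, so that any individual sample or medium can be regenerated in
#' isolation.  The scheme is a fixed affine hash modulo the Mersenne prime
#' 2^31 - 1, which keeps all seeds within R's integer range.
#'
#' @param root integer root seed.
#' @param counter non-negative integer stage counter (may be a vector).
#' @return integer vector of derived seeds in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root, counter) {
  stopifnot(is.numeric(root), length(root) == 1L, is.numeric(counter))
  m <- 2147483647 # 2^31 - 1
  r <- as.numeric(root) %% m
  k <- as.numeric(counter) %% m
  # two rounds of multiply-add; constants are the classic MINSTD multiplier
  # and a 32-bit golden-ratio odd constant reduced mod m
  s <- (r * 48271 + k * 1588635695 + 1) %% m
  s <- (s * 48271 + 11) %% m
  as.integer(ifelse(s == 0, 1, s))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
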