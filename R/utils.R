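# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Scaled complementary error function on the real line via pnorm; used by the
# exponentially-modified-Gaussian decay model. erfc(x) = 2*pnorm(-x*sqrt(2)).
erfc <- function(x) 2 * pnorm(-x * sqrt(2))

# Standard error of the mean.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Derive a stream-specific 32-bit seed from a master seed so that the
# simulators can be called repeatedly from one pipeline seed without
# correlated streams.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 1009L) %% 2147480009L
}
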