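#' @keywords internal
"_PACKAGE"

# clamp a numeric vector to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample skewness (moment estimator)
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# derive a stage seed from a master seed; keeps results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 100000L) * 13L + as.integer(offset) * 1009L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
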