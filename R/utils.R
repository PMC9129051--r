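# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||% .data
#' @importFrom stats coef dnorm glm.fit kmeans lm mad pnorm plogis prcomp
#'   quantile rbinom rnorm runif sd setNames var binomial predict
#' @importFrom utils head modifyList
NULL

# sample skewness (g1 = m3 / m2^{3/2}); NA-free input expected
skewness_g1 <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  z <- x - mean(x)
  m2 <- mean(z^2)
  if (m2 < .Machine$double.eps) return(0)
  mean(z^3) / m2^1.5
}

# numerically stable log(sum(exp(x))) by row for a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# deterministic per-stage seed derivation; stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 1e6) * 2099 + offset * 131 + 17) %% 2147483629L
}

# stop unless `x` is a single finite number in (lo, hi) / [lo, hi]
check_scalar <- function(x, name, lo = -Inf, hi = Inf, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s.",
      name, if (open) "(" else "[", format(lo), format(hi),
      if (open) ")" else "]"
    ))
  }
  invisible(x)
}
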