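#' @importFrom stats rnorm runif rbinom quantile median sd cor prcomp dist
#' @importFrom stats kmeans lm glm.control binomial pnorm pt qchisq pchisq
#' @importFrom stats p.adjust t.test complete.cases coef residuals ks.test
#' @importFrom stats glm.fit lm.fit setNames var aggregate
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a child seed from a parent seed and a stream label, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 1009 + 17) %% 2147483629
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
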