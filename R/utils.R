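#' Derive a reproducible substream seed
#'
#' All randomness in the pipeline flows from a single global seed. Each stage
#' draws its own seed through this deterministic hash of the global seed and a
#' stream label, so stages can be re-run independently without replaying the
#' whole random stream.
#'
#' @param seed integer global seed.
#' @param stream character label of the substream (e.g. `"cohort"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(stream)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# internal: clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# internal: population moments used by several feature families;
# degenerate (zero-variance) inputs return 0 skewness / 0 excess kurtosis
moments_pop <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) {
    return(list(mean = m, var = 0, skew = 0, kurt = 0))
  }
  s <- mean((x - m)^3) / v^1.5
  k <- mean((x - m)^4) / v^2 - 3
  list(mean = m, var = v, skew = s, kurt = k)
}
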