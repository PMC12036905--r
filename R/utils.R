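# Small numerical helpers shared across modules.

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Numerically stable softplus: log(1 + exp(x)) without overflow.
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

frob2 <- function(w) sum(w * w)

#' Derive a named random substream seed
#'
#' All randomness in the package (weight initialization, k-means restarts,
#' synthetic data) flows from a single integer seed.  Each consumer derives
#' its own substream with a stable string tag so that, e.g., changing the
#' number of k-means restarts does not perturb the data generator.
#'
#' @param seed Integer master seed.
#' @param stream Character tag naming the consumer.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "kmeans")
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 65011
  s <- (abs(as.numeric(seed)) %% 1000003) * 2011 + h * 31
  as.integer(s %% 2147483647)
}
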