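#' Ex-Gaussian random samples
#'
#' Sum of a Gaussian and an independent exponential component, the standard
#' descriptive model for response-time distributions. Mean is `mu + tau`.
#' Samples are floored at 1 ms (the Gaussian component can stray below
#' zero for extreme parameter choices; latencies cannot).
#'
#' @param n Number of samples.
#' @param mu,sigma Gaussian component mean and SD (ms).
#' @param tau Exponential component mean (ms).
#' @return Numeric vector of `n` latencies in ms.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  pmax(stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau), 1)
}
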