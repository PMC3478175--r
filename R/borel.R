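#' Borel distribution of branching-process total progeny
#'
#' Probability mass function of the total progeny (avalanche size) of a
#' branching process with `Poisson(sigma)` offspring started from a single
#' ancestor:
#' \deqn{P(S = s) = \frac{e^{-\sigma s}(\sigma s)^{s-1}}{s!}, \quad s = 1, 2, \ldots}
#' Evaluated in log space for numerical stability. This closed form is the
#' exact size law of the unconstrained simulator (see
#' [simulate_branching()]) and serves as its analytic oracle; its tail
#' decays as \eqn{s^{-3/2}} at the critical point `sigma = 1`.
#'
#' @param s Integer avalanche size(s), `>= 1`.
#' @param sigma Branching parameter, in `[0, 1]`.
#' @return Numeric vector of probabilities, same length as `s`.
#' @examples
#' borel_pmf(1, 0)            # 1: no offspring possible
#' borel_pmf(1, 1)            # exp(-1)
#' sum(borel_pmf(1:5000, 0.6))  # ~1: proper distribution for sigma < 1
#' @export
borel_pmf <- function(s, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
      sigma < 0 || sigma > 1)
    abort("invalid parameter: `sigma` must be a single number in [0, 1]")
  if (!is.numeric(s) || any(is.na(s)) || any(s < 1) || any(s != floor(s)))
    abort("invalid parameter: `s` must be integer(s) >= 1")
  if (sigma == 0) return(as.numeric(s == 1))
  exp(-sigma * s + (s - 1) * log(sigma * s) - lgamma(s + 1))
}
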