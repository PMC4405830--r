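#' Beta-binomial log probability mass
#'
#' Log pmf of the beta-binomial: the count of methylated CpGs for a clone
#' whose per-clone methylation probability is drawn from Beta(a, b) and whose
#' N assayable sites are then Bernoulli with that probability.  Closed form
#' via log-beta functions; vectorized over all arguments.
#'
#' @param m methylated count(s), `0 <= m <= N`.
#' @param N assayable sites, `N >= 0`.
#' @param a,b beta shape parameters, both `> 0`.
#' @return log probability (vector).
#' @export
betabin_logpmf <- function(m, N, a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("a and b must be positive")
  if (any(m < 0) || any(m > N)) stop("need 0 <= m <= N")
  if (any(N < 0)) stop("N must be non-negative")
  lchoose(N, m) + lbeta(m + a, N - m + b) - lbeta(a, b)
}

#' Convert between (a, b) and (r, s) beta-binomial parameterizations
#'
#' The mixture model works with the log odds `log(a/b)` (denoted r, the
#' logit of the mean methylation fraction `a/(a+b)`) and the precision
#' `s = a + b` (inverse overdispersion:
#' the beta-binomial approaches the binomial as s grows).
#'
#' @param a,b beta shapes (`> 0`).
#' @param r,s reparameterized values (`s > 0`).
#' @return named list with both parameterizations.
#' @examples
#' rs_to_ab(ab_to_rs(2, 3)$r, ab_to_rs(2, 3)$s)  # a = 2, b = 3
#' @export
ab_to_rs <- function(a, b) {
  stopifnot(all(a > 0), all(b > 0))
  list(r = log(a / b), s = a + b, mu = a / (a + b))
}

#' @rdname ab_to_rs
#' @export
rs_to_ab <- function(r, s) {
  stopifnot(all(s > 0))
  mu <- stats::plogis(r)
  list(a = s * mu, b = s * (1 - mu), mu = mu)
}
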