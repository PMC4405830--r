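#' Q1 score: lower quartile of per-clone percent methylation
#'
#' A simple non-model score for the less-methylated allele: the lower
#' quartile of `100 * m/N` over all sequenced clones.  When two alleles have
#' non-overlapping methylation ranges in roughly equal proportions this
#' approximates the median of the lower allele.  Linear interpolation
#' between order statistics with the (j-1)/(n-1) plotting convention
#' (R quantile type 7); the convention is configurable.
#'
#' @param data data.frame with columns `m`, `N`.
#' @param type quantile type passed to [stats::quantile()] (default 7).
#' @return Q1 in percent.
#' @export
q1_score <- function(data, type = 7) {
  stopifnot(all(c("m", "N") %in% names(data)))
  if (!nrow(as.data.frame(data))) stop("need at least one clone")
  unname(stats::quantile(100 * data$m / data$N, 0.25, type = type))
}

#' Overdispersion relative to the binomial
#'
#' Ratio of the sample variance of per-clone methylated counts to the
#' binomial variance `N * p * (1 - p)` at the pooled methylation fraction.
#' Published clone data typically show a ratio near 4, motivating the
#' beta-binomial.  Clones with missing sites (smaller N) are dropped for
#' this diagnostic only, since mixing unequal N has no clean binomial
#' reference variance; the diagnostic uses the clones at the common
#' (maximal) N.
#'
#' @param data data.frame with columns `m`, `N`.
#' @return variance ratio (a theoretical beta-binomial value is
#'   `1 + (N - 1)/(s + 1)`).
#' @export
overdispersion_ratio <- function(data) {
  stopifnot(all(c("m", "N") %in% names(data)))
  full <- data[data$N == max(data$N), , drop = FALSE]
  if (nrow(full) < 2)
    stop("insufficient data: need >= 2 clones at the common N")
  N <- full$N[1]
  p_hat <- sum(full$m) / sum(full$N)
  if (p_hat <= 0 || p_hat >= 1) return(0)
  stats::var(full$m) / (N * p_hat * (1 - p_hat))
}
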