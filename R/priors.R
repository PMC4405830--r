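#' Prior specification for the two-component beta-binomial mixture
#'
#' Defaults are the published analysis constants: a N(0, 2) prior on the
#' average of the two allele logits, a spike-and-slab prior on the allele
#' difference `d = r2 - r1 >= 0` (point mass 0.5 at d = 0 so the model
#' covers 4qA/4qA, 4qA/4qB and unknown genotypes, gamma(shape 1, rate 0.5)
#' slab), gamma(shape 1, rate 0.025) priors on the overdispersion parameters
#' s1, s2 (prior mean 40), and a fixed 0.5 mixing probability per clone
#' (each of two alleles equally likely to be amplified).
#'
#' The gamma `beta` parameters are read as rates (prior means s = 40,
#' d = 2); the scale reading would give implausible prior means.
#'
#' @param rbar_mean,rbar_sd normal prior on (r1 + r2)/2.
#' @param zero_mass prior point mass on d = 0, in \[0, 1\].
#' @param d_shape,d_rate gamma slab for d > 0.
#' @param s_shape,s_rate gamma prior for s1 and s2.
#' @return list of class `mixture_prior`.
#' @export
mixture_prior <- function(rbar_mean = 0, rbar_sd = 2, zero_mass = 0.5,
                          d_shape = 1, d_rate = 0.5,
                          s_shape = 1, s_rate = 0.025) {
  stopifnot(rbar_sd > 0, zero_mass >= 0, zero_mass <= 1,
            d_shape > 0, d_rate > 0, s_shape > 0, s_rate > 0)
  structure(list(rbar_mean = rbar_mean, rbar_sd = rbar_sd,
                 zero_mass = zero_mass, d_shape = d_shape, d_rate = d_rate,
                 s_shape = s_shape, s_rate = s_rate),
            class = "mixture_prior")
}

#' MCMC schedule
#'
#' Defaults follow the published analysis: 3 parallel chains, 1,000 burn-in
#' steps, 30,000 inference steps, convergence declared when the Gelman-Rubin
#' potential scale reduction factor is below 1.01 for every monitored
#' parameter.  On non-convergence the inference run is doubled up to
#' `max_extensions` times before giving up with a warning.
#'
#' @param n_chains number of chains (>= 2 for the PSRF).
#' @param burn_in burn-in iterations per chain.
#' @param n_iter retained iterations per chain.
#' @param seed integer seed controlling the whole run.
#' @param psrf_threshold convergence threshold on the PSRF.
#' @param max_extensions maximum number of doublings of `n_iter`.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, burn_in = 1000, n_iter = 30000,
                        seed = 1, psrf_threshold = 1.01, max_extensions = 3) {
  stopifnot(n_chains >= 2, burn_in > 0, n_iter > 0, psrf_threshold > 1,
            max_extensions >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_iter = as.integer(n_iter),
                 seed = as.integer(seed),
                 psrf_threshold = psrf_threshold,
                 max_extensions = as.integer(max_extensions)),
            class = "mcmc_config")
}
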