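#' Full allele-specific methylation fit for one sample
#'
#' Runs the two-component mixture, the mono-allelic model, the Q1 score and
#' the overdispersion diagnostic on one sample's clone counts.
#'
#' @param x a `methylation_matrix` from [call_sample()] /
#'   [read_matrix_tsv()], or a data.frame with columns `m`, `N`.
#' @param prior a [mixture_prior()].
#' @param config an [mcmc_config()].
#' @return object of class `allele_fit`: list with `mixture`
#'   (`posterior_summary`), `mono` (`monoallelic_fit`), `q1`,
#'   `overdispersion` (NA when fewer than 2 equal-N clones), `counts`.
#' @export
fit_alleles <- function(x, prior = mixture_prior(), config = mcmc_config()) {
  counts <- if (inherits(x, "methylation_matrix")) clone_counts(x) else x
  stopifnot(all(c("m", "N") %in% names(counts)))
  mixture <- sample_posterior(counts, prior, config)
  mono <- fit_monoallelic(counts, prior,
                          mcmc_config(n_chains = config$n_chains,
                                      burn_in = config$burn_in,
                                      n_iter = config$n_iter,
                                      seed = config$seed + 1L,
                                      psrf_threshold = config$psrf_threshold,
                                      max_extensions = config$max_extensions))
  od <- tryCatch(overdispersion_ratio(counts), error = function(e) NA_real_)
  structure(list(mixture = mixture, mono = mono,
                 q1 = q1_score(counts), overdispersion = od,
                 counts = counts), class = "allele_fit")
}

#' @export
print.allele_fit <- function(x, ...) {
  cat(sprintf(paste0("<allele_fit: allele 1 = %.1f%%, allele 2 = %.1f%%, ",
                     "mono = %.1f%%, Q1 = %.1f%%, overdispersion = %.2f>\n"),
              x$mixture$allele1_percent, x$mixture$allele2_percent,
              x$mono$percent, x$q1, x$overdispersion))
  invisible(x)
}

#' Write a posterior summary JSON for a fitted sample
#'
#' @param fit an `allele_fit` from [fit_alleles()].
#' @param path output JSON path.
#' @param sample_id optional sample label.
#' @return `path`, invisibly.
#' @export
write_posterior_json <- function(fit, path, sample_id = NULL) {
  stopifnot(inherits(fit, "allele_fit"))
  mx <- fit$mixture
  jsonlite::write_json(list(
    sample_id = sample_id,
    allele1_percent = mx$allele1_percent,
    allele2_percent = mx$allele2_percent,
    mono_percent = fit$mono$percent,
    q1_percent = fit$q1,
    p_d_gt_0 = mx$p_d_gt_0,
    overdispersion_ratio = fit$overdispersion,
    psrf = as.list(mx$psrf),
    converged = mx$converged,
    low_confidence = mx$low_confidence,
    n_clones = mx$n_clones,
    assign_p1 = mx$assign_p1,
    seed = mx$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
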