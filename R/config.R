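#' Read prior/MCMC configuration from a JSON file
#'
#' Accepts a JSON object with optional `prior` and `mcmc` sub-objects whose
#' fields match [mixture_prior()] and [mcmc_config()]; absent fields keep
#' the defaults (which equal the published analysis constants).
#'
#' @param path JSON config path.
#' @return list with elements `prior` (a `mixture_prior`) and `mcmc` (an
#'   `mcmc_config`).
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), c("prior", "mcmc"))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  list(prior = do.call(mixture_prior, as.list(cfg$prior)),
       mcmc = do.call(mcmc_config, as.list(cfg$mcmc)))
}
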