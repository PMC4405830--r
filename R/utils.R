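#' Logit and inverse-logit on the percent scale
#'
#' Methylation levels are modelled on the logit scale `y = log(a/b)` and
#' reported as percentages.  `logit_percent()` maps a percent in (0, 100) to
#' the logit scale; `expit_percent()` inverts it.
#'
#' @param percent numeric vector of percentages in (0, 100).
#' @param y numeric vector of logit-scale values.
#' @return numeric vector.
#' @examples
#' expit_percent(logit_percent(7))  # 7
#' @export
logit_percent <- function(percent) {
  stopifnot(is.numeric(percent), all(percent > 0 & percent < 100))
  stats::qlogis(percent / 100)
}

#' @rdname logit_percent
#' @export
expit_percent <- function(y) 100 * stats::plogis(y)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: one RNG-derived sub-seed per independent task, all < 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
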