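#' Select the lower-methylation allele (and assay) per sample
#'
#' For each sample, within each assay the lesser-allele logit is taken; when
#' both the 4qA and 4qA-L assays were run, the assay giving the smaller `y`
#' is kept (recording which), so `y` always tracks the least-methylated
#' amplifiable 4qA-type allele.
#'
#' @param fits data.frame with one row per (sample, assay): columns
#'   `sample_id`, `assay`, `y` (posterior mean logit of the lesser allele for
#'   that assay) and any passthrough columns (family, disease class, cell
#'   type).
#' @return data.frame with one row per sample: the input row with the
#'   smallest `y`, plus `percent = 100 * plogis(y)` and `chosen_assay`.
#' @export
select_lower_allele <- function(fits) {
  stopifnot(all(c("sample_id", "assay", "y") %in% names(fits)))
  if (!nrow(fits)) stop("no per-assay fits supplied")
  picked <- do.call(rbind, lapply(split(fits, fits$sample_id), function(df) {
    df[which.min(df$y), , drop = FALSE]
  }))
  picked$chosen_assay <- picked$assay
  picked$percent <- expit_percent(picked$y)
  rownames(picked) <- NULL
  picked[order(picked$sample_id), ]
}

#' Fit the cohort linear mixed-effects model
#'
#' Maximum-likelihood fit (not REML, because fixed-effect structures are
#' compared by likelihood-ratio tests) of the logit-scale methylation value
#' `y` on cell type x disease class cell means, an additive assay offset,
#' and a family random intercept:
#' `y ~ 0 + cell_type:disease_class + assay + (1 | family_id)`.
#' Disease classes are `Control`, `NonMfst` (nonmanifesting carriers),
#' `FSHD_b` (affected with a nonmanifesting first-degree relative in the
#' cohort) and `FSHD_a` (affected without one).
#'
#' @param samples data.frame with columns `sample_id`, `family_id`,
#'   `disease_class`, `cell_type`, `assay`, `y`.
#' @param collapse_classes optional character vector of disease classes to
#'   merge into one level (e.g. `c("NonMfst", "FSHD_b")` for the
#'   nonmanifesting-vs-affected test).
#' @param collapse_cell_type merge myocyte and blood into one level.
#' @param include_assay include the additive assay fixed effect (dropped
#'   automatically when only one assay is present).
#' @return object of class `lme_fit`: the `lmerMod` in `$model`, plus
#'   `fixef`, `se`, `loglik`, `n_par`, `var_family`, `var_resid` and the
#'   collapse flags.
#' @export
fit_lme <- function(samples, collapse_classes = NULL,
                    collapse_cell_type = FALSE, include_assay = TRUE) {
  need <- c("sample_id", "family_id", "disease_class", "cell_type", "assay", "y")
  stopifnot(all(need %in% names(samples)))
  df <- samples
  if (length(unique(df$family_id)) < 2) stop("need >= 2 families")
  df$disease_class <- as.character(df$disease_class)
  if (!is.null(collapse_classes)) {
    merged <- paste(sort(collapse_classes), collapse = "+")
    df$disease_class[df$disease_class %in% collapse_classes] <- merged
  }
  df$cell_type <- if (collapse_cell_type) "all" else as.character(df$cell_type)
  df$cell <- interaction(df$cell_type, df$disease_class, drop = TRUE)
  use_assay <- include_assay && length(unique(df$assay)) > 1
  form <- if (use_assay) y ~ 0 + cell + assay + (1 | family_id)
          else y ~ 0 + cell + (1 | family_id)
  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  X <- lme4::getME(fit, "X")
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design; cells: ",
         paste(levels(df$cell), collapse = ", "))
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(model = fit, data = df,
                 fixef = est, se = stats::setNames(se, names(est)),
                 loglik = as.numeric(stats::logLik(fit)),
                 n_par = attr(stats::logLik(fit), "df"),
                 var_family = vc$vcov[vc$grp == "family_id"],
                 var_resid = vc$vcov[vc$grp == "Residual"],
                 collapse_classes = collapse_classes,
                 collapse_cell_type = collapse_cell_type,
                 include_assay = use_assay), class = "lme_fit")
}

#' Likelihood-ratio test between nested LME fits
#'
#' `statistic = 2 * (ll_full - ll_reduced)`, df the parameter-count
#' difference, p from the upper chi-squared tail.  A reduced model must be
#' nested in the full model (fewer parameters on the same data).  A slightly
#' negative statistic from optimizer noise is truncated at zero after a
#' refit attempt.
#'
#' @param full,reduced `lme_fit` objects from [fit_lme()].
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lme_fit"), inherits(reduced, "lme_fit"))
  df <- full$n_par - reduced$n_par
  if (df < 0) stop("models are not nested: 'full' has fewer parameters")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < 0) {
    # refit the full model from another optimizer before truncating
    refit <- tryCatch(
      lme4::lmer(stats::formula(full$model), data = full$data, REML = FALSE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (!is.null(refit))
      stat <- max(stat, 2 * (as.numeric(stats::logLik(refit)) - reduced$loglik))
    stat <- max(0, stat)
  }
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Exact paired sign test over family cohorts
#'
#' Within each family cohort, compares the nonmanifesting member(s) against
#' the manifesting member(s).  Where a side has two members, every choice of
#' which member to include is evaluated; the test is reported for each
#' choice combination and the p value is shared whenever all choices give
#' the same sign vector.  Ties (exactly equal percents) are excluded from n.
#' Two-sided exact binomial p:
#' `p = min(1, 2 * sum_{k >= max(n_pos, n - n_pos)} C(n, k) 0.5^n)`.
#'
#' @param pairs data.frame with columns `cohort`, `status` (`manifesting` or
#'   `nonmanifesting`) and `percent`; multiple rows per (cohort, status)
#'   represent duplicate subjects.
#' @return list with `n_positive`, `n`, `p` (for the first choice),
#'   `consistent` (TRUE if every duplicate choice gives the same sign
#'   vector), and `choices` (data.frame of per-choice results).
#' @export
sign_test <- function(pairs) {
  stopifnot(all(c("cohort", "status", "percent") %in% names(pairs)))
  if (!nrow(pairs)) stop("no data for sign test")
  cohorts <- split(pairs, pairs$cohort)
  per <- lapply(cohorts, function(df) {
    man <- df$percent[df$status == "manifesting"]
    non <- df$percent[df$status == "nonmanifesting"]
    if (!length(man) || !length(non))
      stop("cohort ", df$cohort[1], " lacks one side of the pair")
    expand.grid(man = man, non = non)
  })
  combos <- expand.grid(lapply(per, function(g) seq_len(nrow(g))))
  exact_p <- function(n_pos, n) {
    if (n == 0) return(NA_real_)
    k <- max(n_pos, n - n_pos)
    min(1, 2 * sum(stats::dbinom(k:n, n, 0.5)))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(ci) {
    signs <- vapply(seq_along(per), function(g) {
      row <- per[[g]][combos[ci, g], ]
      sign(row$non - row$man)
    }, numeric(1))
    n <- sum(signs != 0)
    n_pos <- sum(signs > 0)
    data.frame(choice = ci, n_positive = n_pos, n = n,
               p = exact_p(n_pos, n), signs = paste(signs, collapse = ""))
  }))
  list(n_positive = res$n_positive[1], n = res$n[1], p = res$p[1],
       consistent = length(unique(res$signs)) == 1,
       choices = res[, c("choice", "n_positive", "n", "p")])
}

#' D4Z4 repeat units from the EcoRI/BlnI fragment size
#'
#' `RU = (kb - 2)/3.3`, rounded to the nearest half repeat unit (ties round
#' up), as used for genotyping tables; fragments of 2 kb or less carry no
#' repeat and are invalid.
#'
#' @param kb EcoRI/BlnI restriction fragment size in kb (vectorized).
#' @return repeat units, a multiple of 0.5.
#' @examples
#' ru_from_fragment(c(28, 30))  # 8, 8.5
#' @export
ru_from_fragment <- function(kb) {
  stopifnot(is.numeric(kb))
  if (any(kb <= 2)) stop("invalid fragment: kb must exceed 2")
  floor(2 * (kb - 2) / 3.3 + 0.5) / 2
}

#' Back-transformed subgroup means with asymmetric intervals
#'
#' Subgroup fixed effects (cell type x disease class cells, at the baseline
#' assay) transformed from the logit scale back to percentages; the interval
#' endpoints `expit(est +/- SE)` are asymmetric about `expit(est)` except at
#' 0 on the logit scale.
#'
#' @param fit an `lme_fit` from [fit_lme()].
#' @return data.frame with `cell`, `estimate_logit`, `se`, `percent`,
#'   `lower_percent`, `upper_percent`.
#' @export
group_report <- function(fit) {
  stopifnot(inherits(fit, "lme_fit"))
  keep <- grep("^cell", names(fit$fixef))
  est <- fit$fixef[keep]
  se <- fit$se[keep]
  data.frame(cell = sub("^cell", "", names(est)),
             estimate_logit = unname(est), se = unname(se),
             percent = unname(expit_percent(est)),
             lower_percent = unname(expit_percent(est - se)),
             upper_percent = unname(expit_percent(est + se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Load the packaged familial-cohort fixture table
#'
#' Nine family cohorts of FSHD1-affected (manifesting) and nonmanifesting
#' carriers sharing the same contracted 4qA allele: percent methylation per
#' subject (4qA assay), the EcoRI/BlnI fragment size and the derived repeat
#' units.  Long format: one row per subject.
#'
#' @return data.frame with columns `cohort`, `status`, `percent`, `kb`, `ru`.
#' @export
read_cohort_table <- function() {
  path <- system.file("extdata", "familial_cohorts.csv", package = "d4z4meth")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort-level comparison report
#'
#' Fits the full LME, the reduced models used for the standard
#' likelihood-ratio tests (Control vs NonMfst collapsed, NonMfst vs FSHD_b
#' collapsed, FSHD_a vs FSHD_b collapsed, cell types collapsed), and
#' returns the tests plus the back-transformed subgroup report.
#'
#' @param samples as for [fit_lme()].
#' @return list with `full` (`lme_fit`), `tests` (named list of [lrt()]
#'   results), `groups` (from [group_report()]).
#' @export
cohort_compare <- function(samples) {
  full <- fit_lme(samples)
  reduced <- list(
    control_vs_nonmfst = fit_lme(samples, collapse_classes = c("Control", "NonMfst")),
    nonmfst_vs_fshd_b = fit_lme(samples, collapse_classes = c("NonMfst", "FSHD_b")),
    fshd_a_vs_fshd_b = fit_lme(samples, collapse_classes = c("FSHD_a", "FSHD_b")),
    cell_type = fit_lme(samples, collapse_cell_type = TRUE))
  tests <- lapply(reduced, function(red) lrt(full, red))
  list(full = full, tests = tests, groups = group_report(full))
}
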