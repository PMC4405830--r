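#' Simulate per-clone methylated counts from one or two beta-binomial alleles
#'
#' Each clone's allele is drawn with probability `mix_prob` for allele 1,
#' its per-clone methylation probability from Beta(a_i, b_i) with
#' `a_i = s_i * mu_i`, and its methylated count binomially.  Missing sites
#' (1-3 per affected clone, as seen in practice) reduce N.  Allele means are
#' clipped to (1e-4, 1 - 1e-4) so degenerate 0/1 inputs stay valid beta
#' parameters.  Overdispersion relative to the binomial is
#' `1 + (N - 1)/(s + 1)`, so `s = (N - 1)/3 - 1` gives the 4x inflation
#' typical of clone data.
#'
#' @param n_clones total clones.
#' @param mu length-2 allele mean methylation fractions (allele 1 first);
#'   give both equal (or `mix_prob = 1`) for a mono-allelic sample.
#' @param s length-2 overdispersion parameters.
#' @param assay_n CpGs in the assay (56 for 4qA, 30 for 4qA-L, 59 for the
#'   DUX4 5' assay).
#' @param missing_rate per-site missing-call rate; per-clone missing sites
#'   are capped at 3.
#' @param mix_prob probability a clone originates from allele 1.
#' @param seed integer seed (mandatory: generators are pure functions of
#'   their spec and seed).
#' @return data.frame with `clone_id`, `allele` (true label), `m`, `N`.
#' @export
simulate_counts <- function(n_clones = 50, mu = c(0.1, 0.7), s = c(15, 15),
                            assay_n = 56, missing_rate = 0.02,
                            mix_prob = 0.5, seed) {
  stopifnot(length(mu) == 2, length(s) == 2, all(s > 0),
            missing_rate >= 0, missing_rate <= 1, !missing(seed))
  set.seed(as.integer(seed))
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  allele <- ifelse(stats::runif(n_clones) < mix_prob, 1L, 2L)
  n_miss <- pmin(stats::rbinom(n_clones, assay_n, missing_rate), 3L)
  N <- assay_n - n_miss
  p <- stats::rbeta(n_clones, s[allele] * mu[allele],
                    s[allele] * (1 - mu[allele]))
  m <- stats::rbinom(n_clones, N, p)
  data.frame(clone_id = sprintf("clone_%03d", seq_len(n_clones)),
             allele = allele, m = m, N = N, stringsAsFactors = FALSE)
}

# Internal: per-clone, per-site methylation states (1/0/NA) consistent with
# the beta-binomial count model; NA marks sites simulated as undetected.
simulate_clone_states <- function(n_clones, mu, s, n_cpg, missing_rate,
                                  mix_prob = 0.5) {
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  allele <- ifelse(stats::runif(n_clones) < mix_prob, 1L, 2L)
  states <- matrix(NA_integer_, n_clones, n_cpg)
  for (i in seq_len(n_clones)) {
    p <- stats::rbeta(1, s[allele[i]] * mu[allele[i]],
                      s[allele[i]] * (1 - mu[allele[i]]))
    states[i, ] <- stats::rbinom(n_cpg, 1, p)
    n_miss <- min(stats::rbinom(1, n_cpg, missing_rate), 3L)
    if (n_miss > 0) states[i, sample.int(n_cpg, n_miss)] <- NA_integer_
  }
  list(states = states, allele = allele)
}

#' Simulate cloned bisulfite-PCR reads for an assay
#'
#' Renders per-clone methylation states into bisulfite-converted sequences
#' of the assay reference (CpG C kept when methylated, converted to T when
#' not; every non-CpG C converted to T), applies iid substitution errors,
#' marks simulated missing sites by destroying the CpG (C to A, so calling
#' reports no CpG detected), injects contaminant clones carrying the homolog
#' bases at every diagnostic position, and reverse-complements a random half
#' of the reads to exercise orientation handling.
#'
#' @param assay a [reference_assay()] whose `diagnostic_positions` carry a
#'   `homolog_base` column (e.g. from [synthetic_reference()]).
#' @param n_clones number of target-locus clones.
#' @param mu,s,missing_rate,mix_prob as in [simulate_counts()].
#' @param error_rate per-base substitution error probability.
#' @param contaminant_fraction fraction of additional homolog clones,
#'   relative to `n_clones`.
#' @param seed integer seed.
#' @return list with `reads` (named character vector), `truth` (data.frame
#'   `clone_id`, `allele` (NA for contaminants), `contaminant`,
#'   `orientation`) and `states` (true state matrix for target clones,
#'   1/0/NA).
#' @export
simulate_clone_sequences <- function(assay, n_clones = 20, mu = c(0.1, 0.7),
                                     s = c(15, 15), error_rate = 0,
                                     contaminant_fraction = 0,
                                     missing_rate = 0, mix_prob = 0.5, seed) {
  stopifnot(inherits(assay, "reference_assay"), !missing(seed))
  set.seed(as.integer(seed))
  ref <- strsplit(assay$sequence, "")[[1]]
  cpg <- assay$cpg_positions
  sim <- simulate_clone_states(n_clones, mu, s, length(cpg), missing_rate,
                               mix_prob)
  n_cont <- round(n_clones * contaminant_fraction)
  dp <- assay$diagnostic_positions
  if (n_cont > 0 && !("homolog_base" %in% names(dp)))
    stop("assay lacks homolog_base annotation; cannot simulate contaminants")

  render <- function(states_row, contaminant) {
    chars <- ref
    if (contaminant)
      chars[dp$pos] <- dp$homolog_base
    chars[chars == "C"] <- "T"          # bisulfite conversion, non-CpG C
    meth <- which(states_row == 1L)
    chars[cpg[meth]] <- "C"             # protected 5mC reads as C
    miss <- which(is.na(states_row))
    chars[cpg[miss]] <- "A"             # CpG not detected at these sites
    if (error_rate > 0) {
      hit <- which(stats::runif(length(chars)) < error_rate)
      for (h in hit)
        chars[h] <- sample(setdiff(c("A", "C", "G", "T"), chars[h]), 1)
    }
    paste(chars, collapse = "")
  }

  reads <- character(0)
  truth <- list()
  for (i in seq_len(n_clones)) {
    id <- sprintf("clone_%03d", i)
    reads[id] <- render(sim$states[i, ], FALSE)
    truth[[id]] <- data.frame(clone_id = id, allele = sim$allele[i],
                              contaminant = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_cont)) {
    id <- sprintf("contaminant_%03d", i)
    p <- stats::rbeta(1, 2, 2)
    reads[id] <- render(stats::rbinom(length(cpg), 1, p), TRUE)
    truth[[id]] <- data.frame(clone_id = id, allele = NA_integer_,
                              contaminant = TRUE, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  flip <- stats::runif(length(reads)) < 0.5
  reads[flip] <- vapply(reads[flip], function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1))
  truth$orientation <- ifelse(flip, "reverse-complemented", "as-given")
  rownames(truth) <- NULL
  list(reads = reads, truth = truth, states = sim$states)
}

#' Write simulated reads and their ground truth to files
#'
#' @param sim result of [simulate_clone_sequences()].
#' @param fasta output FASTA path.
#' @param truth_json optional path for the ground-truth JSON.
#' @return `fasta`, invisibly.
#' @export
write_simulated_fasta <- function(sim, fasta, truth_json = NULL) {
  seqs <- Biostrings::DNAStringSet(sim$reads)
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(truth_json))
    jsonlite::write_json(list(truth = sim$truth, states = sim$states),
                         truth_json, auto_unbox = TRUE, digits = NA)
  invisible(fasta)
}

#' Simulate a family-structured cohort sample table
#'
#' Generates one logit-scale methylation value per sample:
#' `y = class/cell fixed effect + assay offset + family intercept + residual`,
#' with families built the way familial FSHD cohorts are collected: pairs of
#' an affected subject with either a nonmanifesting relative (classes
#' `FSHD_b` + `NonMfst`) or a healthy control (`FSHD_a` + `Control`).
#'
#' The default cohort layout mirrors the published study design: 9 families
#' of an affected subject with a nonmanifesting relative (4 assayed in
#' myocytes, 5 in blood) and 11 families of an affected subject with a
#' healthy control (8 myocyte, 3 blood); each family is assayed in one cell
#' type.  Default effects are published-scale group means on the percent scale
#' (Control 71%, NonMfst 25%, affected 7%), no cell-type effect (published
#' myocyte/blood differences were not significant), a +0.5 logit 4qA-L assay
#' offset (the 4qA-L assay reads higher), family SD 0.5 and residual SD 0.5
#' on the logit scale.
#'
#' @param n_families_b families of affected + nonmanifesting pairs.
#' @param n_families_a families of affected + control pairs.
#' @param n_blood_b,n_blood_a how many families of each kind are assayed in
#'   blood (the rest in myocytes); assigned deterministically to the last
#'   families of each group.
#' @param class_percent named percent-scale means for `Control`, `NonMfst`,
#'   `FSHD_a`, `FSHD_b`.
#' @param cell_type_effect additive logit effect of blood vs myocyte.
#' @param assay_effect additive logit effect of the 4qA-L assay vs 4qA.
#' @param family_sd,resid_sd random-intercept and residual SDs (logit scale).
#' @param prop_aql fraction of samples measured with the 4qA-L assay.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `family_id`, `disease_class`,
#'   `cell_type`, `assay`, `y`, `percent` and the generating `truth` as an
#'   attribute.
#' @export
simulate_cohort <- function(n_families_b = 9, n_families_a = 11,
                            n_blood_b = 5, n_blood_a = 3,
                            class_percent = c(Control = 71, NonMfst = 25,
                                              FSHD_a = 7, FSHD_b = 7),
                            cell_type_effect = 0, assay_effect = 0.5,
                            family_sd = 0.5, resid_sd = 0.5,
                            prop_aql = 0.1, seed) {
  stopifnot(!missing(seed), n_families_a + n_families_b >= 2,
            n_blood_b <= n_families_b, n_blood_a <= n_families_a,
            all(c("Control", "NonMfst", "FSHD_a", "FSHD_b") %in%
                  names(class_percent)))
  set.seed(as.integer(seed))
  class_logit <- logit_percent(class_percent)
  fam_classes <- c(rep(list(c("FSHD_b", "NonMfst")), n_families_b),
                   rep(list(c("FSHD_a", "Control")), n_families_a))
  n_fam <- length(fam_classes)
  fam_cell <- c(rep("myocyte", n_families_b - n_blood_b),
                rep("blood", n_blood_b),
                rep("myocyte", n_families_a - n_blood_a),
                rep("blood", n_blood_a))
  rows <- list()
  for (f in seq_len(n_fam)) {
    u <- stats::rnorm(1, 0, family_sd)
    for (cls in fam_classes[[f]]) {
      assay <- if (stats::runif(1) < prop_aql) "4qA-L" else "4qA"
      y <- class_logit[[cls]] +
        (if (fam_cell[f] == "blood") cell_type_effect else 0) +
        (if (assay == "4qA-L") assay_effect else 0) +
        u + stats::rnorm(1, 0, resid_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("S%02d_%s", f, cls),
        family_id = sprintf("F%02d", f),
        disease_class = cls, cell_type = fam_cell[f], assay = assay,
        y = y, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$percent <- expit_percent(out$y)
  attr(out, "truth") <- list(class_percent = class_percent,
                             cell_type_effect = cell_type_effect,
                             assay_effect = assay_effect,
                             family_sd = family_sd, resid_sd = resid_sd)
  out
}
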