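#' Call CpG methylation states from a clone alignment
#'
#' For each reference CpG position, the aligned read base determines the
#' call: C is methylated (`METH`), T unmethylated (`UNMETH`), and a gap, N or
#' any other base is `MISSING` (no CpG detected at that site).
#'
#' @param alignment a `clone_alignment` from [align_clone()].
#' @param clone_id identifier carried through to the result.
#' @return an object of class `clone_call_vector`: list with `clone_id`,
#'   `calls` (character vector over `METH`/`UNMETH`/`MISSING`, one per assay
#'   CpG), `m` (count METH), `n_called` (non-missing), `percent_identity`,
#'   `n_diagnostic_mismatches`, `orientation`, and (after [filter_clone()])
#'   `pass_filter`/`rejection_reason`.
#' @export
call_cpgs <- function(alignment, clone_id = "clone") {
  assay <- alignment$assay
  cols <- alignment_columns(alignment)
  calls <- vapply(assay$cpg_positions, function(p) {
    row <- cols[!is.na(cols$ref_pos) & cols$ref_pos == p, ]
    if (!nrow(row)) return("MISSING")
    switch(row$read[1], C = "METH", T = "UNMETH", "MISSING")
  }, character(1))
  structure(list(
    clone_id = clone_id,
    calls = calls,
    m = sum(calls == "METH"),
    n_called = sum(calls != "MISSING"),
    percent_identity = compute_identity(alignment),
    n_diagnostic_mismatches = count_diagnostic_mismatches(alignment),
    orientation = alignment$orientation,
    pass_filter = NA,
    rejection_reason = NULL), class = "clone_call_vector")
}

#' Apply the clone QC filters
#'
#' Filters follow the assay's specificity rules, in order of precedence:
#' a clone with more diagnostic-position mismatches than allowed is a
#' non-target homolog (`HOMOLOG`); otherwise identity below the threshold
#' rejects it (`LOW_IDENTITY`, default >98% as for the published assays);
#' otherwise more missing CpG calls than tolerated (`TOO_MANY_MISSING`,
#' default at most 3 sites, matching the 1-3 missing sites seen in practice)
#' rejects it.
#'
#' @param vec a `clone_call_vector` from [call_cpgs()].
#' @param expected_cpg_count assay CpG count (needed for the missing-site
#'   rule).
#' @param min_identity minimum bisulfite-aware identity (default 0.98).
#' @param max_missing maximum missing CpG calls (default 3).
#' @param max_diagnostic_mismatches maximum tolerated diagnostic mismatches
#'   (default 0).
#' @return the vector with `pass_filter` and `rejection_reason` set.
#' @export
filter_clone <- function(vec, expected_cpg_count = length(vec$calls),
                         min_identity = 0.98, max_missing = 3,
                         max_diagnostic_mismatches = 0) {
  stopifnot(inherits(vec, "clone_call_vector"))
  reason <- NULL
  if (vec$n_diagnostic_mismatches > max_diagnostic_mismatches) {
    reason <- "HOMOLOG"
  } else if (vec$percent_identity < min_identity) {
    reason <- "LOW_IDENTITY"
  } else if ((expected_cpg_count - vec$n_called) > max_missing) {
    reason <- "TOO_MANY_MISSING"
  }
  vec$pass_filter <- is.null(reason)
  vec$rejection_reason <- reason
  vec
}

#' Align, call and filter every clone of a sample
#'
#' The end-to-end calling step: aligns each read in both orientations against
#' the bisulfite-converted template, calls CpG states, computes identity and
#' diagnostic mismatches, and applies the QC filters.
#'
#' @param reads named character vector or `DNAStringSet` of clone sequences;
#'   names are clone ids and must be unique.
#' @param assay a [reference_assay()].
#' @param sample_id sample label.
#' @param min_identity,max_missing,max_diagnostic_mismatches see
#'   [filter_clone()].
#' @return an object of class `methylation_matrix`: list with `assay` name,
#'   `sample_id`, `expected_cpg_count`, and `clones` (list of
#'   `clone_call_vector`).
#' @export
call_sample <- function(reads, assay, sample_id = "sample",
                        min_identity = 0.98, max_missing = 3,
                        max_diagnostic_mismatches = 0) {
  reads <- stats::setNames(as.character(reads), names(reads))
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must have unique names (clone ids)")
  clones <- lapply(names(reads), function(id) {
    aln <- align_clone(reads[[id]], assay)
    filter_clone(call_cpgs(aln, clone_id = id),
                 expected_cpg_count = assay$expected_cpg_count,
                 min_identity = min_identity, max_missing = max_missing,
                 max_diagnostic_mismatches = max_diagnostic_mismatches)
  })
  structure(list(assay = assay$name, sample_id = sample_id,
                 expected_cpg_count = assay$expected_cpg_count,
                 clones = clones), class = "methylation_matrix")
}

#' Per-sample coverage and QC summary
#'
#' Coverage is the fraction of expected CpGs actually called across passing
#' clones (the published assays report on average >99%).
#'
#' @param matrix a `methylation_matrix` from [call_sample()].
#' @return list with `coverage`, `mean_identity` (over passing clones),
#'   `n_pass`, and `n_fail` (named counts by rejection reason).
#' @export
coverage_summary <- function(matrix) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  if (!length(matrix$clones)) stop("no clones in matrix")
  pass <- Filter(function(cl) isTRUE(cl$pass_filter), matrix$clones)
  fail <- Filter(function(cl) !isTRUE(cl$pass_filter), matrix$clones)
  if (!length(pass)) stop("no clones pass filters: no data")
  called <- sum(vapply(pass, `[[`, numeric(1), "n_called"))
  reasons <- vapply(fail, `[[`, character(1), "rejection_reason")
  list(coverage = called / (length(pass) * matrix$expected_cpg_count),
       mean_identity = mean(vapply(pass, `[[`, numeric(1), "percent_identity")),
       n_pass = length(pass),
       n_fail = c(table(factor(reasons,
                               levels = c("LOW_IDENTITY", "HOMOLOG",
                                          "TOO_MANY_MISSING")))))
}

#' Extract per-clone methylated counts from a call matrix
#'
#' Reduces passing clones to the (m, N) pairs consumed by the mixture model:
#' m methylated CpGs out of N assayable (non-missing) sites.
#'
#' @param matrix a `methylation_matrix`.
#' @param passing_only drop clones failing QC (default TRUE).
#' @return data.frame with columns `clone_id`, `m`, `N`.
#' @export
clone_counts <- function(matrix, passing_only = TRUE) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  cl <- matrix$clones
  if (passing_only) cl <- Filter(function(x) isTRUE(x$pass_filter), cl)
  if (!length(cl)) stop("no clones available")
  data.frame(clone_id = vapply(cl, `[[`, character(1), "clone_id"),
             m = vapply(cl, `[[`, numeric(1), "m"),
             N = vapply(cl, `[[`, numeric(1), "n_called"),
             stringsAsFactors = FALSE)
}

#' @export
print.methylation_matrix <- function(x, ...) {
  n_pass <- sum(vapply(x$clones, function(cl) isTRUE(cl$pass_filter), logical(1)))
  cat(sprintf("<methylation_matrix '%s' assay %s: %d clones (%d pass), %d CpGs>\n",
              x$sample_id, x$assay, length(x$clones), n_pass,
              x$expected_cpg_count))
  invisible(x)
}
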