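#' Read clone sequences from FASTA
#'
#' @param path FASTA file of cloned bisulfite-PCR sequences.
#' @return named character vector of sequences (names are clone ids).
#' @export
read_clone_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequences in FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate clone ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(seqs), ids)
}

#' Write / read a per-clone CpG call matrix as TSV
#'
#' One row per clone with columns `clone_id`, `pass_filter`, `identity`,
#' `rejection_reason`, then one column per CpG index (`cpg_1` ... `cpg_K`,
#' 1-based left to right) holding 1 (methylated), 0 (unmethylated) or NA
#' (no CpG detected).  `read_matrix_tsv(write_matrix_tsv(x))` reproduces the
#' matrix.
#'
#' @param matrix a `methylation_matrix` from [call_sample()].
#' @param path output TSV path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns a `methylation_matrix`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  k <- matrix$expected_cpg_count
  rows <- lapply(matrix$clones, function(cl) {
    states <- ifelse(cl$calls == "METH", 1L,
                     ifelse(cl$calls == "UNMETH", 0L, NA_integer_))
    cbind(data.frame(clone_id = cl$clone_id,
                     pass_filter = isTRUE(cl$pass_filter),
                     identity = cl$percent_identity,
                     rejection_reason = cl$rejection_reason %||% "",
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(t(states)), paste0("cpg_", seq_len(k))))
  })
  df <- do.call(rbind, rows)
  attr(df, "assay") <- matrix$assay
  utils::write.table(
    cbind(data.frame(assay = matrix$assay, sample_id = matrix$sample_id,
                     stringsAsFactors = FALSE), df),
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = "NA"),
    error = function(e) stop("malformed matrix TSV '", path, "': ",
                             conditionMessage(e)))
  need <- c("assay", "sample_id", "clone_id", "pass_filter", "identity",
            "rejection_reason")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("matrix TSV '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  cpg_cols <- grep("^cpg_\\d+$", names(df), value = TRUE)
  cpg_cols <- cpg_cols[order(as.integer(sub("cpg_", "", cpg_cols)))]
  if (!length(cpg_cols)) stop("matrix TSV '", path, "' has no cpg_ columns")
  clones <- lapply(seq_len(nrow(df)), function(i) {
    states <- as.integer(df[i, cpg_cols])
    calls <- ifelse(is.na(states), "MISSING",
                    ifelse(states == 1L, "METH", "UNMETH"))
    reason <- df$rejection_reason[i]
    structure(list(
      clone_id = as.character(df$clone_id[i]),
      calls = calls,
      m = sum(calls == "METH"),
      n_called = sum(calls != "MISSING"),
      percent_identity = df$identity[i],
      n_diagnostic_mismatches = NA_integer_,
      orientation = NA_character_,
      pass_filter = isTRUE(df$pass_filter[i]),
      rejection_reason = if (is.na(reason) || !nzchar(reason)) NULL else reason),
      class = "clone_call_vector")
  })
  structure(list(assay = df$assay[1], sample_id = as.character(df$sample_id[1]),
                 expected_cpg_count = length(cpg_cols),
                 clones = clones), class = "methylation_matrix")
}

#' Write a QC report JSON for a called sample
#'
#' @param matrix a `methylation_matrix`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(matrix, path) {
  qc <- coverage_summary(matrix)
  jsonlite::write_json(
    list(sample_id = matrix$sample_id, assay = matrix$assay,
         expected_cpg_count = matrix$expected_cpg_count,
         n_clones = length(matrix$clones),
         n_pass = qc$n_pass, n_fail = as.list(qc$n_fail),
         coverage = qc$coverage, mean_identity = qc$mean_identity),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
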