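#' Assay reference sequence with CpG and diagnostic annotation
#'
#' A `reference_assay` bundles the unconverted top strand of a bisulfite-PCR
#' amplicon with the ordered positions of its CpG cytosines and, optionally,
#' positions whose base distinguishes the target 4q locus from non-4q/10q
#' homologs.  The three named assays interrogate 56 (`4qA`), 30 (`4qA-L`) and
#' 59 (`DUX4_5prime`) CpGs respectively.
#'
#' Positions are 1-based R indices into `sequence`.  BED annotation read via
#' [read_reference_assay()] is converted from 0-based half-open coordinates.
#'
#' @param name assay name; one of `"4qA"`, `"4qA-L"`, `"DUX4_5prime"`, or a
#'   free-form label for user-supplied assays.
#' @param sequence character scalar, DNA over `A,C,G,T`.
#' @param cpg_positions strictly increasing integer vector; `sequence` must
#'   read `"CG"` at each position.  If `NULL`, positions are inferred by
#'   scanning for `"CG"`.
#' @param diagnostic_positions optional data.frame with columns `pos` and
#'   `base` (the base expected at `pos` on the target locus).  Empty by
#'   default, in which case homolog filtering degrades to identity filtering.
#' @return an object of class `reference_assay`.
#' @export
reference_assay <- function(name, sequence,
                            cpg_positions = NULL,
                            diagnostic_positions = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence must be over the alphabet {A,C,G,T}")
  if (is.null(cpg_positions)) {
    cpg_positions <- as.integer(gregexpr("CG", sequence)[[1]])
    if (length(cpg_positions) == 1 && cpg_positions[1] == -1L)
      cpg_positions <- integer(0)
  }
  cpg_positions <- as.integer(cpg_positions)
  if (is.unsorted(cpg_positions, strictly = TRUE))
    stop("cpg_positions must be strictly increasing")
  chars <- strsplit(sequence, "")[[1]]
  bad <- cpg_positions[chars[cpg_positions] != "C" |
                       chars[pmin(cpg_positions + 1L, length(chars))] != "G" |
                       cpg_positions >= length(chars)]
  if (length(bad))
    stop("not a CpG at position(s): ", paste(bad, collapse = ", "))
  if (is.null(diagnostic_positions)) {
    diagnostic_positions <- data.frame(pos = integer(0),
                                       base = character(0),
                                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("pos", "base") %in% names(diagnostic_positions)))
  expected <- c(`4qA` = 56L, `4qA-L` = 30L, DUX4_5prime = 59L)
  if (name %in% names(expected) && length(cpg_positions) != expected[[name]])
    stop(sprintf("assay '%s' must have %d CpGs, got %d",
                 name, expected[[name]], length(cpg_positions)))
  structure(list(name = name,
                 sequence = sequence,
                 cpg_positions = cpg_positions,
                 diagnostic_positions = diagnostic_positions,
                 expected_cpg_count = length(cpg_positions)),
            class = "reference_assay")
}

#' @export
print.reference_assay <- function(x, ...) {
  cat(sprintf("<reference_assay '%s': %d bp, %d CpGs, %d diagnostic position(s)>\n",
              x$name, nchar(x$sequence), x$expected_cpg_count,
              nrow(x$diagnostic_positions)))
  invisible(x)
}

#' Bisulfite-convert a reference into the expected-read template
#'
#' Bisulfite treatment deaminates unmethylated cytosines to uracil (read as
#' T) while 5-methylcytosine is protected.  On the template this makes every
#' non-CpG C a deterministic T and every CpG C an ambiguous `Y` (C if
#' methylated, T if not).
#'
#' @param assay a [reference_assay()].
#' @return character scalar over `A,C,G,T,Y`, same length as the reference.
#' @export
bisulfite_convert_reference <- function(assay) {
  stopifnot(inherits(assay, "reference_assay"))
  chars <- strsplit(assay$sequence, "")[[1]]
  is_c <- chars == "C"
  chars[is_c] <- "T"
  chars[assay$cpg_positions] <- "Y"
  paste(chars, collapse = "")
}

#' Generate a synthetic assay reference fixture
#'
#' Builds a random amplicon with the requested number of CpGs at irregular
#' spacings and a set of homolog-diagnostic positions (default 5, echoing the
#' handful of sequence changes that distinguish 4q from its 10q homolog).
#' The sequence contains no CpG other than the annotated ones, so positions
#' inferred by scanning agree with the annotation.  The returned assay also
#' carries a `homolog_bases` column in `diagnostic_positions`: the base the
#' contaminating homolog carries at each diagnostic position.
#'
#' Real 4qA/4qA-L/DUX4 references are external; this fixture only reproduces
#' their CpG counts and QC structure.
#'
#' @param name assay name; for the three named assays the CpG count is fixed
#'   (56, 30, 59).
#' @param length amplicon length in bp.
#' @param n_cpg number of CpGs (ignored for the named assays).
#' @param n_diagnostic number of diagnostic positions.
#' @param seed integer seed.
#' @return a [reference_assay()] whose `diagnostic_positions` has columns
#'   `pos`, `base`, `homolog_base`.
#' @export
synthetic_reference <- function(name = "4qA", length = 1000, n_cpg = NULL,
                                n_diagnostic = 5, seed = 1) {
  expected <- c(`4qA` = 56L, `4qA-L` = 30L, DUX4_5prime = 59L)
  if (name %in% names(expected)) n_cpg <- expected[[name]]
  if (is.null(n_cpg)) stop("n_cpg required for unnamed assays")
  stopifnot(length >= 4 * n_cpg + 2 * n_diagnostic + 20)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # GC-rich background, then break every accidental CpG.
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c(0.2, 0.3, 0.3, 0.2))
  repeat {
    cg <- which(chars[-length] == "C" & chars[-1] == "G")
    if (!length(cg)) break
    chars[cg + 1L] <- sample(c("A", "T", "C"), length(cg), replace = TRUE)
  }
  # place CpGs at irregular spacings, keeping 2 bp clearance
  usable <- seq(10L, length - 10L)
  repeat {
    pos <- sort(sample(usable, n_cpg))
    if (all(diff(pos) >= 3)) break
  }
  chars[pos] <- "C"
  chars[pos + 1L] <- "G"
  # breaking accidental CpGs created by the insertions (e.g. ..C[C G]..)
  repeat {
    cg <- setdiff(which(chars[-length] == "C" & chars[-1] == "G"), pos)
    if (!length(cg)) break
    for (p in cg) {
      if ((p + 1L) %in% pos || p %in% (pos + 1L)) chars[p] <- "A" else chars[p + 1L] <- "T"
    }
  }
  # diagnostic positions: bisulfite-stable bases (A/G/T, never C) away from CpGs
  taken <- sort(unique(c(pos, pos + 1L)))
  cand <- setdiff(which(chars %in% c("A", "G", "T")), c(taken, taken - 1L))
  diag_pos <- sort(sample(cand, n_diagnostic))
  homolog <- vapply(chars[diag_pos], function(b)
    sample(setdiff(c("A", "G", "T"), b), 1), character(1))
  assay <- reference_assay(name, paste(chars, collapse = ""),
                           cpg_positions = which(chars[-length] == "C" & chars[-1] == "G"),
                           diagnostic_positions = data.frame(
                             pos = diag_pos,
                             base = chars[diag_pos],
                             homolog_base = unname(homolog),
                             stringsAsFactors = FALSE))
  stopifnot(assay$expected_cpg_count == n_cpg)
  assay
}

#' Read a reference assay from FASTA plus optional BED CpG annotation
#'
#' @param fasta path to a single-record reference FASTA.
#' @param bed optional path to a BED file (0-based half-open) of CpG cytosine
#'   positions; if omitted, CpGs are inferred by scanning for `"CG"`.
#' @param name assay name (defaults to the FASTA record id).
#' @param diagnostic_positions as for [reference_assay()].
#' @return a [reference_assay()].
#' @export
read_reference_assay <- function(fasta, bed = NULL, name = NULL,
                                 diagnostic_positions = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1) stop("reference FASTA must contain exactly one record")
  cpg <- NULL
  if (!is.null(bed)) {
    tab <- utils::read.table(bed, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    cpg <- sort(as.integer(tab[[2]])) + 1L  # BED start is 0-based
  }
  reference_assay(name %||% names(seqs)[1],
                  as.character(seqs[[1]]),
                  cpg_positions = cpg,
                  diagnostic_positions = diagnostic_positions)
}
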