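# Bisulfite-aware pairwise alignment of clone reads against the converted
# reference template.  Alignment itself is delegated to
# Biostrings::pairwiseAlignment with a custom substitution matrix in which a
# read C or T opposite a template Y (a CpG cytosine) scores as a match.

# Substitution matrix over {A,C,G,T,Y,N}: match +1, mismatch -2, Y matches
# C and T, N is neutral (0) against everything.
bisulfite_submat <- function(match = 1, mismatch = -2) {
  letters <- c("A", "C", "G", "T", "Y", "N")
  m <- matrix(mismatch, 6, 6, dimnames = list(letters, letters))
  diag(m) <- match
  m["Y", c("C", "T")] <- match
  m[c("C", "T"), "Y"] <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Align a clone read against a bisulfite-converted assay template
#'
#' Global (end-to-end) alignment with affine gaps (match +1, mismatch -2,
#' gap open -5, gap extend -1).  The template has every non-CpG C converted
#' to T and every CpG C as `Y`; a read T or C opposite `Y` scores as a match
#' (unmethylated/methylated).  Both the given orientation and the reverse
#' complement are aligned and the higher-scoring orientation kept, so calling
#' is orientation-invariant.
#'
#' @param read character scalar or `DNAString`: the clone sequence
#'   (alphabet `A,C,G,T,N`).
#' @param assay a [reference_assay()].
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @return an object of class `clone_alignment`: list with `template` and
#'   `read` (gapped character scalars of equal length), `score`,
#'   `orientation` (`"as-given"` or `"reverse-complemented"`), and `assay`.
#' @export
align_clone <- function(read, assay, gap_open = 5, gap_extend = 1) {
  stopifnot(inherits(assay, "reference_assay"))
  read <- toupper(as.character(read))
  if (!nzchar(read)) stop("cannot align an empty read")
  if (grepl("[^ACGTN]", read)) stop("read alphabet must be {A,C,G,T,N}")

  template <- bisulfite_convert_reference(assay)
  submat <- bisulfite_submat()
  pat <- Biostrings::DNAString(template)
  fwd <- Biostrings::DNAString(read)
  rev <- Biostrings::reverseComplement(fwd)

  aln_fwd <- Biostrings::pairwiseAlignment(
    pat, fwd, type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aln_rev <- Biostrings::pairwiseAlignment(
    pat, rev, type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)

  if (Biostrings::score(aln_fwd) >= Biostrings::score(aln_rev)) {
    aln <- aln_fwd; orientation <- "as-given"
  } else {
    aln <- aln_rev; orientation <- "reverse-complemented"
  }
  structure(list(
    template = as.character(Biostrings::alignedPattern(aln)),
    read = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln),
    orientation = orientation,
    assay = assay), class = "clone_alignment")
}

# Internal: per-alignment-column bookkeeping.  Returns a data.frame with one
# row per alignment column: template char, read char, 1-based reference
# position (NA in template-gap columns), and whether the column lies in the
# end-trimmed core (first through last column where both sequences have a
# residue; terminal gap-only overhangs are excluded from identity).
alignment_columns <- function(alignment) {
  tch <- strsplit(alignment$template, "")[[1]]
  rch <- strsplit(alignment$read, "")[[1]]
  stopifnot(length(tch) == length(rch))
  ref_pos <- cumsum(tch != "-")
  ref_pos[tch == "-"] <- NA_integer_
  both <- which(tch != "-" & rch != "-")
  core <- logical(length(tch))
  if (length(both)) core[min(both):max(both)] <- TRUE
  data.frame(template = tch, read = rch, ref_pos = ref_pos, core = core,
             stringsAsFactors = FALSE)
}

#' Bisulfite-aware percent identity of an aligned clone
#'
#' Identity is the fraction of matching columns among aligned reference
#' columns, where bisulfite-expected substitutions count as matches: a read C
#' or T opposite a template `Y` (CpG cytosine), and the deterministic
#' non-CpG C-to-T conversions (already encoded as T in the template).
#' Gap-only columns at the sequence ends (primer-trimming tolerance) are
#' excluded from the denominator; internal gaps and read N count as
#' mismatches.
#'
#' @param alignment a `clone_alignment` from [align_clone()].
#' @return fraction in \[0, 1\].
#' @export
compute_identity <- function(alignment) {
  cols <- alignment_columns(alignment)
  ref_cols <- cols[cols$core & cols$template != "-", ]
  if (!nrow(ref_cols)) return(0)
  match <- with(ref_cols,
    ifelse(template == "Y", read %in% c("C", "T"), read == template))
  mean(match)
}

# Internal: number of diagnostic positions where the read clearly carries a
# different base than the (bisulfite-converted) expected base.  Gaps and N
# are not evaluable and do not count as mismatches.
count_diagnostic_mismatches <- function(alignment) {
  dp <- alignment$assay$diagnostic_positions
  if (!nrow(dp)) return(0L)
  cols <- alignment_columns(alignment)
  n <- 0L
  for (k in seq_len(nrow(dp))) {
    expected <- dp$base[k]
    if (expected == "C") expected <- "T"  # non-CpG C reads as T after conversion
    row <- cols[!is.na(cols$ref_pos) & cols$ref_pos == dp$pos[k], ]
    if (!nrow(row)) next
    got <- row$read[1]
    if (got %in% c("A", "C", "G", "T") && got != expected) n <- n + 1L
  }
  n
}
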