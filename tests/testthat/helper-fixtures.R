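# Shared fixtures, built in code at test time.

# Small synthetic assay (fast alignments); full-size 4qA assay for tests
# that need the published CpG counts.
tiny_assay <- function(seed = 7) {
  synthetic_reference("toy", length = 260, n_cpg = 8, n_diagnostic = 3,
                      seed = seed)
}

assay_4qa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_reference("4qA", seed = 11)
    cache
  }
})

# Construct a clone_call_vector directly (for filter tests).
fake_call_vector <- function(m, n_called, n_cpg, identity = 1,
                             n_diag_mismatch = 0) {
  calls <- c(rep("METH", m), rep("UNMETH", n_called - m),
             rep("MISSING", n_cpg - n_called))
  structure(list(clone_id = "fake", calls = calls, m = m,
                 n_called = n_called, percent_identity = identity,
                 n_diagnostic_mismatches = n_diag_mismatch,
                 orientation = "as-given", pass_filter = NA,
                 rejection_reason = NULL), class = "clone_call_vector")
}

# Independent quadratic-time global affine-gap aligner (Gotoh), used as an
# oracle for alignment scores on toy pairs.  Same scoring rules as
# align_clone: match +1, mismatch -2, Y matches C/T, gap open 5 + extend 1
# per base (first gap base costs open + extend).
gotoh_score <- function(a, b, match = 1, mismatch = -2,
                        gap_open = 5, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  sub <- function(x, y) {
    if (x == y || (x == "Y" && y %in% c("C", "T")) ||
        (y == "Y" && x %in% c("C", "T"))) match else mismatch
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub(a[i - 1], b[j - 1])
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Render a read from an assay + per-site states with no error (independent
# of simulate_clone_sequences, for round-trip checks).
perfect_read <- function(assay, states = rep(1L, assay$expected_cpg_count)) {
  chars <- strsplit(assay$sequence, "")[[1]]
  chars[chars == "C"] <- "T"
  chars[assay$cpg_positions[states == 1L]] <- "C"
  paste(chars, collapse = "")
}
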