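test_that("bisulfite conversion of the reference template", {
  assay <- reference_assay("toy2", "ACGTCA", cpg_positions = 2)
  expect_equal(bisulfite_convert_reference(assay), "AYGTTA")

  no_c <- reference_assay("toy0", "AGGTTAGA")
  expect_equal(bisulfite_convert_reference(no_c), "AGGTTAGA")

  tpl <- bisulfite_convert_reference(assay_4qa())
  expect_equal(lengths(regmatches(tpl, gregexpr("Y", tpl))), 56)
  expect_false(grepl("C", tpl))  # every non-CpG C converted
  expect_equal(nchar(tpl), nchar(assay_4qa()$sequence))
})

test_that("reference_assay validates CpG annotation and named-assay counts", {
  expect_error(reference_assay("x", "ACGT", cpg_positions = 3), "CpG")
  expect_error(reference_assay("x", "ACXT"), "alphabet")
  expect_error(synthetic_reference("4qA", seed = 1, n_cpg = 10) |>
                 (\(a) reference_assay("4qA", a$sequence,
                                       cpg_positions = a$cpg_positions[1:10]))(),
               "56")
  # scanning finds exactly the annotated CpGs in the synthetic fixture
  a <- assay_4qa()
  rescan <- reference_assay("4qA", a$sequence)
  expect_identical(rescan$cpg_positions, a$cpg_positions)
})

test_that("alignment is bisulfite-aware, end-to-end, orientation-robust", {
  assay <- tiny_assay()
  read <- perfect_read(assay)  # fully methylated clone
  aln <- align_clone(read, assay)
  expect_equal(aln$orientation, "as-given")
  expect_equal(compute_identity(aln), 1.0)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  aln_rc <- align_clone(rc, assay)
  expect_equal(aln_rc$orientation, "reverse-complemented")
  expect_equal(aln_rc$read, aln$read)

  expect_error(align_clone("", assay), "empty")
})

test_that("alignment scores match an independent quadratic-time aligner", {
  assay <- tiny_assay()
  template <- bisulfite_convert_reference(assay)
  read <- perfect_read(assay)
  # internal 3-base deletion away from the ends
  del <- paste0(substr(read, 1, 99), substr(read, 103, nchar(read)))
  aln <- align_clone(del, assay)
  expect_equal(aln$score, gotoh_score(template, del))
  # the alignment contains exactly one 3-base gap in the read
  gaps <- regmatches(aln$read, gregexpr("-+", aln$read))[[1]]
  expect_equal(gaps, "---")

  # substitution-only toy pair
  sub <- paste0(substr(read, 1, 49), "A", substr(read, 51, nchar(read)))
  aln2 <- align_clone(sub, assay)
  expect_equal(aln2$score, gotoh_score(template, sub))
})

test_that("CpG calling maps C/T/gap to METH/UNMETH/MISSING", {
  assay <- tiny_assay()
  states <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  read <- perfect_read(assay, states)
  vec <- call_cpgs(align_clone(read, assay))
  expect_equal(vec$calls,
               ifelse(states == 1L, "METH", "UNMETH"))
  expect_equal(vec$m, 4)
  expect_equal(vec$n_called, 8)

  # a base other than C/T at the 3rd CpG (no CpG detected) is MISSING
  p <- assay$cpg_positions[3]
  lost <- paste0(substr(read, 1, p - 1), "A", substr(read, p + 1, nchar(read)))
  vec2 <- call_cpgs(align_clone(lost, assay))
  expect_equal(vec2$calls[3], "MISSING")
  expect_equal(vec2$n_called, 7)
})

test_that("identity arithmetic and Monte-Carlo identity under sequencing error", {
  assay <- tiny_assay()
  read <- perfect_read(assay)
  # two true mismatches at non-CpG positions
  chars <- strsplit(read, "")[[1]]
  ok <- setdiff(seq_along(chars),
                c(assay$cpg_positions, assay$cpg_positions + 1L))
  chars[ok[10]] <- setdiff(c("A", "C", "G", "T"), chars[ok[10]])[1]
  chars[ok[40]] <- setdiff(c("A", "C", "G", "T"), chars[ok[40]])[1]
  aln <- align_clone(paste(chars, collapse = ""), assay)
  expect_equal(compute_identity(aln), 1 - 2 / nchar(read))

  # mean identity tracks 1 - error rate (Y columns absorb a third of their
  # errors as apparent methylation changes, a ~0.1% effect here)
  sim <- simulate_clone_sequences(assay_4qa(), n_clones = 60,
                                  error_rate = 0.005, seed = 21)
  ids <- vapply(sim$reads, function(r)
    compute_identity(align_clone(r, assay_4qa())), numeric(1))
  expect_equal(mean(ids), 0.995, tolerance = 0.002)
})

test_that("clone filters apply homolog, identity and missing rules in order", {
  n_cpg <- 56
  pass <- filter_clone(fake_call_vector(10, 55, n_cpg, identity = 0.999),
                       expected_cpg_count = n_cpg)
  expect_true(pass$pass_filter)
  expect_null(pass$rejection_reason)

  low <- filter_clone(fake_call_vector(10, 56, n_cpg, identity = 0.95),
                      expected_cpg_count = n_cpg)
  expect_false(low$pass_filter)
  expect_equal(low$rejection_reason, "LOW_IDENTITY")

  miss <- filter_clone(fake_call_vector(10, 52, n_cpg, identity = 0.999),
                       expected_cpg_count = n_cpg)
  expect_equal(miss$rejection_reason, "TOO_MANY_MISSING")

  # three missing sites are tolerated
  ok3 <- filter_clone(fake_call_vector(10, 53, n_cpg, identity = 0.999),
                      expected_cpg_count = n_cpg)
  expect_true(ok3$pass_filter)

  # homolog takes precedence over low identity
  hom <- filter_clone(fake_call_vector(10, 56, n_cpg, identity = 0.90,
                                       n_diag_mismatch = 2),
                      expected_cpg_count = n_cpg)
  expect_equal(hom$rejection_reason, "HOMOLOG")
})

test_that("coverage summary counts called sites over passing clones", {
  n_cpg <- 56
  mat <- structure(list(assay = "4qA", sample_id = "s1",
                        expected_cpg_count = n_cpg,
                        clones = list(
                          filter_clone(fake_call_vector(5, 56, n_cpg),
                                       expected_cpg_count = n_cpg),
                          filter_clone(fake_call_vector(5, 55, n_cpg),
                                       expected_cpg_count = n_cpg))),
                   class = "methylation_matrix")
  qc <- coverage_summary(mat)
  expect_equal(qc$coverage, 111 / 112)
  expect_equal(qc$n_pass, 2)

  all_fail <- mat
  all_fail$clones <- list(
    filter_clone(fake_call_vector(5, 56, n_cpg, identity = 0.5),
                 expected_cpg_count = n_cpg))
  expect_error(coverage_summary(all_fail), "no data")
})

test_that("matrix TSV round-trips and FASTA rejects duplicate ids", {
  assay <- tiny_assay()
  sim <- simulate_clone_sequences(assay, n_clones = 3, missing_rate = 0.05,
                                  seed = 3)
  mat <- call_sample(sim$reads, assay, sample_id = "s1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(mat, tsv)
  back <- read_matrix_tsv(tsv)
  expect_equal(back$sample_id, "s1")
  expect_equal(back$expected_cpg_count, assay$expected_cpg_count)
  for (i in seq_along(mat$clones)) {
    expect_identical(back$clones[[i]]$calls, unname(mat$clones[[i]]$calls))
    expect_equal(back$clones[[i]]$m, mat$clones[[i]]$m)
    expect_equal(back$clones[[i]]$n_called, mat$clones[[i]]$n_called)
    expect_equal(back$clones[[i]]$pass_filter, mat$clones[[i]]$pass_filter)
  }
  # writing the re-read matrix reproduces the file byte-for-byte
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(back, tsv2)
  expect_identical(readLines(tsv), readLines(tsv2))

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), fa)
  expect_error(read_clone_fasta(fa), "duplicate")
})

test_that("calling recovers simulated states exactly and is orientation-invariant", {
  assay <- assay_4qa()
  sim <- simulate_clone_sequences(assay, n_clones = 12, error_rate = 0,
                                  contaminant_fraction = 0, missing_rate = 0,
                                  seed = 9)
  mat <- call_sample(sim$reads, assay)
  for (i in seq_len(12)) {
    cl <- mat$clones[[i]]
    expect_true(cl$pass_filter)
    rec <- as.integer(cl$calls == "METH")
    expect_identical(rec, unname(sim$states[i, ]))
    expect_equal(cl$orientation, sim$truth$orientation[i])
  }
})

test_that("homolog contaminants are rejected with reason HOMOLOG", {
  assay <- assay_4qa()
  sim <- simulate_clone_sequences(assay, n_clones = 10, error_rate = 0,
                                  contaminant_fraction = 0.3, seed = 13)
  mat <- call_sample(sim$reads, assay)
  reasons <- vapply(mat$clones, function(cl)
    if (is.null(cl$rejection_reason)) "pass" else cl$rejection_reason,
    character(1))
  expect_identical(reasons == "HOMOLOG", sim$truth$contaminant)
})
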