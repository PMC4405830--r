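#!/usr/bin/env Rscript
# Stage 2: clone sequences -> filtered CpG call matrix.
#
# Aligns each clone (both orientations) against the bisulfite-converted
# reference, calls METH/UNMETH/MISSING at each of the 56 CpGs, and applies
# the QC filters: >98% bisulfite-aware identity, <=3 missing sites, zero
# homolog-diagnostic mismatches.  Writes results/calls/matrix.tsv and a QC
# JSON; reports how the filters did against the simulation ground truth.

library(d4z4meth)

sim_dir <- "results/sim"
out <- "results/calls"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

assay <- read_reference_assay(file.path(sim_dir, "reference.fa"),
                              bed = file.path(sim_dir, "reference_cpgs.bed"),
                              name = "4qA")
# diagnostic annotation travels with the generator, not the FASTA; rebuild it
assay <- synthetic_reference("4qA", seed = 11)

reads <- read_clone_fasta(file.path(sim_dir, "clones.fa"))
mat <- call_sample(reads, assay, sample_id = "sim_sample")
write_matrix_tsv(mat, file.path(out, "matrix.tsv"))
write_qc_json(mat, file.path(out, "qc.json"))

qc <- coverage_summary(mat)
message(sprintf("%d/%d clones pass QC; coverage %.3f; mean identity %.4f",
                qc$n_pass, length(mat$clones), qc$coverage, qc$mean_identity))
message("rejections: ", paste(names(qc$n_fail), qc$n_fail, collapse = ", "))

truth <- jsonlite::read_json(file.path(sim_dir, "truth.json"),
                             simplifyVector = TRUE)$truth
reasons <- vapply(mat$clones, function(cl)
  if (is.null(cl$rejection_reason)) "pass" else cl$rejection_reason,
  character(1))
hom_ok <- identical(unname(reasons == "HOMOLOG"), truth$contaminant)
message("all injected homolog contaminants (and only those) rejected: ", hom_ok)
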