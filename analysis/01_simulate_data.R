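#!/usr/bin/env Rscript
# Stage 1: generate the synthetic inputs for the whole analysis.
#
# Produces, under results/sim/:
#   reference.fa / reference_cpgs.bed  - synthetic 4qA assay (56 CpGs,
#                                        5 homolog-diagnostic positions)
#   clones.fa / truth.json             - 40 cloned bisulfite reads from two
#                                        alleles (10% / 70% mean methylation,
#                                        s = 15, ~4x binomial variance), 0.2%
#                                        sequencing error, 10% homolog
#                                        contaminants, 2% missing sites
#   counts.csv                         - bare (m, N) clone counts
#   cohort.csv                         - family-structured cohort table
#                                        (published-scale group means)

library(d4z4meth)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

assay <- synthetic_reference("4qA", seed = 11)
writeLines(c(">4qA_synthetic", assay$sequence), file.path(out, "reference.fa"))
write.table(data.frame("4qA_synthetic", assay$cpg_positions - 1L,
                       assay$cpg_positions),
            file.path(out, "reference_cpgs.bed"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

sim <- simulate_clone_sequences(assay, n_clones = 40, mu = c(0.1, 0.7),
                                s = c(15, 15), error_rate = 0.002,
                                contaminant_fraction = 0.1,
                                missing_rate = 0.02, seed = 101)
write_simulated_fasta(sim, file.path(out, "clones.fa"),
                      truth_json = file.path(out, "truth.json"))
message(sprintf("wrote %d reads (%d contaminants) to %s/clones.fa",
                nrow(sim$truth), sum(sim$truth$contaminant), out))

counts <- simulate_counts(n_clones = 50, mu = c(0.1, 0.7), s = c(15, 15),
                          assay_n = 56, missing_rate = 0.02, seed = 102)
write.csv(counts, file.path(out, "counts.csv"), row.names = FALSE)

cohort <- simulate_cohort(seed = 103)
write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)
message(sprintf("cohort: %d samples in %d families",
                nrow(cohort), length(unique(cohort$family_id))))
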