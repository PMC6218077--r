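#!/usr/bin/env Rscript
# Base-composition homogeneity by codon position, with and without a
# lineage-specific third-position bias, and the RY-recoded matrix that
# suppresses it. Run after 01_simulate_gene_families.R.

suppressPackageStartupMessages(library(rhodup))
dir.create("results/composition", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

truth <- simulate_gene_tree(rh1_species_tree(), "B6", seed = seed)

report <- NULL
for (biased in c(FALSE, TRUE)) {
  sm <- if (biased) {
    simulation_model(third_position_freq_override = c(0.05, 0.45, 0.45, 0.05),
                     override_taxa = c("Clupeo", "Osteo", "Hiodon"))
  } else {
    simulation_model()
  }
  aln <- simulate_alignment(truth, sm, seed = seed)
  for (p in 1:3) {
    ct <- composition_homogeneity_test(aln, p)
    report <- rbind(report, data.frame(
      dataset = ifelse(biased, "biased_pos3", "homogeneous"),
      codon_position = p, chi2 = round(ct$statistic, 3), df = ct$df,
      p_value = signif(ct$p_value, 4)))
  }
  if (biased) {
    write_fasta_alignment(aln, "results/composition/biased_alignment.fasta")
    write_fasta_alignment(ry_recode(aln, 3),
                          "results/composition/biased_alignment_ry3.fasta")
  }
}
write.table(report, "results/composition/homogeneity_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Chi-squared homogeneity by codon position:\n")
print(report, row.names = FALSE)
cat("\nWith the lineage-specific bias the third position departs from\n",
    "homogeneity while positions 1-2 do not; the RY-recoded matrix is\n",
    "written alongside for downstream analysis.\n", sep = "")
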