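#!/usr/bin/env Rscript
# Simulate the study cohorts: a 60-sample human GSC-like cohort with three
# planted accessibility clusters, a 9-sample mouse cohort with three
# groups, and their homolog pairing with an 80% shared regulatory program.
# Writes the cohort matrices and ground truth under results/cohort/.

suppressPackageStartupMessages(library(gscatac))
seed <- 20260921
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

paired <- generate_paired_species(mouse_cohort_config(seed = seed),
                                  cohort_config(seed = seed),
                                  shared_program_frac = 0.8, seed = seed)
human <- paired$human; mouse <- paired$mouse

write_bed(human$peaks, file.path(out, "human_peaks.bed"))
write_bed(mouse$peaks, file.path(out, "mouse_peaks.bed"))
write_matrix_tsv(human$counts$raw, file.path(out, "human_counts.tsv"),
                 id_col = "peak_id")
write_matrix_tsv(human$expression, file.path(out, "human_expression.tsv"),
                 id_col = "gene_id")
write_genes_tsv(human$genes, file.path(out, "human_genes.tsv"))
write_genes_tsv(mouse$genes, file.path(out, "mouse_genes.tsv"))
data.table::fwrite(paired$homologs, file.path(out, "homologs.tsv"), sep = "\t")
data.table::fwrite(data.frame(sample = names(human$true_labels),
                              cluster = human$true_labels),
                   file.path(out, "human_true_labels.tsv"), sep = "\t")
write_config_yaml(human$config, file.path(out, "human_config.yaml"))
saveRDS(paired, file.path(out, "paired_cohort.rds"))  # working object for later steps

cat("Simulated", nrow(human$peaks), "human peaks x",
    length(human$true_labels), "samples and", nrow(mouse$peaks),
    "mouse peaks x", length(mouse$true_labels), "samples.\n")
cat("Planted cluster-specific peaks per human cluster:",
    paste(lengths(human$cluster_specific_peaks), collapse = "/"), "\n")
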