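#!/usr/bin/env Rscript
# Peak-to-gene linkage: candidate distal pairs within +/-0.5 Mbp (excluding
# +/-3 kbp), Pearson correlation of accessibility and expression, empirical
# null z-scores, BH correction at FDR < 0.05, and recall of planted links.

suppressPackageStartupMessages(library(gscatac))
paired <- readRDS("results/cohort/paired_cohort.rds")
human <- paired$human

pairs <- candidate_peak_gene_pairs(human$peaks, human$genes)
links <- link_peaks_to_genes(human$counts$logcpm, human$expression, pairs)
data.table::fwrite(links, "results/peak_gene_links.tsv", sep = "\t")

truth_key <- paste(human$true_links$peak_id, human$true_links$gene_id)
got_key <- paste(links$peak_id, links$gene_id)[links$significant]
cat(sprintf("%d candidate pairs; %d significant links at FDR<0.05.\n",
            nrow(links), sum(links$significant)))
cat(sprintf("Recall of the %d planted links: %.3f; precision %.3f.\n",
            length(truth_key), mean(truth_key %in% got_key),
            mean(got_key %in% truth_key)))
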