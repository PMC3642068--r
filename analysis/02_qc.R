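#!/usr/bin/env Rscript
# Reproducibility QC: all-sample Pearson correlation matrices and
# average-linkage dendrograms (distance 1 - r) per contrast. Replicates of
# the same condition and fraction should cluster as siblings.

suppressPackageStartupMessages(library(polysomeAPV))
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

for (nm in c("exvivo", "activated")) {
  ds <- align_paired_dataset(
    read_expression_tsv(sprintf("results/data/%s_cytosolic.tsv", nm)),
    read_expression_tsv(sprintf("results/data/%s_polysome.tsv", nm)),
    read_annotation_tsv(sprintf("results/data/%s_annotation.tsv", nm)))
  joint <- cbind(ds$cytosolic, ds$polysome)
  cc <- correlation_matrix(joint, "pearson")
  write.table(data.frame(sample_id = rownames(cc), cc, check.names = FALSE),
              sprintf("results/qc/%s_correlations.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hc <- hierarchical_cluster(cc)
  dendrogram_newick(hc, sprintf("results/qc/%s_dendrogram.nwk", nm))
  sib <- sibling_pairs(hc)
  message(sprintf("%s: min off-diagonal r = %.3f; sibling pairs: %s", nm,
                  min(cc[upper.tri(cc)]),
                  paste(apply(sib, 1, function(i)
                    paste(hc$labels[i], collapse = "+")), collapse = ", ")))
}
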