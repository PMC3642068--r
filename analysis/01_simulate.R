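#!/usr/bin/env Rscript
# Generate the synthetic study: paired cytosolic / polysome-associated
# expression for two CD4+ T cell subsets (Foxp3+ regulatory vs Foxp3-
# conventional), each profiled ex vivo and after activation, in biological
# duplicate. Translational differences between subsets are modest ex vivo
# and extensive after activation, so the two contrasts are simulated with
# 20 and 700 spiked genes respectively (|effect| = 2 log2); each dataset
# also carries transcriptional-only spikes that the cytosolic correction
# must remove. A linked secondary fold-change table stands in for an
# external dataset with elevated eIF4E activity.

suppressPackageStartupMessages(library(polysomeAPV))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

contrast_sets <- list(
  exvivo = simulation_params(
    group_labels = c("Tconv_ex", "Treg_ex"), contrast_group = "Treg_ex",
    n_spiked_up = 10, n_spiked_down = 10, seed = seed),
  activated = simulation_params(
    group_labels = c("Tconv_act", "Treg_act"), contrast_group = "Treg_act",
    seed = seed + 1L))

for (nm in names(contrast_sets)) {
  sim <- simulate_dataset(contrast_sets[[nm]])
  write_expression_tsv(sim$dataset$cytosolic,
                       sprintf("results/data/%s_cytosolic.tsv", nm))
  write_expression_tsv(sim$dataset$polysome,
                       sprintf("results/data/%s_polysome.tsv", nm))
  write_annotation_tsv(sim$dataset$annotation,
                       sprintf("results/data/%s_annotation.tsv", nm))
  truth <- data.frame(
    gene_id = c(names(sim$truth$spiked_up), names(sim$truth$spiked_down),
                names(sim$truth$transcriptional)),
    class = rep(c("spiked_up", "spiked_down", "transcriptional"),
                c(length(sim$truth$spiked_up),
                  length(sim$truth$spiked_down),
                  length(sim$truth$transcriptional))),
    effect = c(sim$truth$spiked_up, sim$truth$spiked_down,
               sim$truth$transcriptional))
  write.table(truth, sprintf("results/data/%s_truth.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: %d genes, %d sample pairs, %d + %d spiked, %d transcriptional",
    nm, length(sim$truth$gene_ids), nrow(sim$dataset$pairing),
    length(sim$truth$spiked_up), length(sim$truth$spiked_down),
    length(sim$truth$transcriptional)))

  if (nm == "activated") {
    # external dataset probing the same axis (85% sign concordance)
    sec <- simulate_secondary_effects(sim$truth, seed = seed + 2L)
    write_effects_tsv(sec, "results/data/secondary_effects.tsv")
    col <- simulate_gene_sets(sim$truth, seed = seed + 3L)
    write_gmt(col, "results/data/gene_sets.gmt")
    message(sprintf("secondary table (%d genes) and %d gene sets written",
                    length(sec), length(col$terms)))
  }
}
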