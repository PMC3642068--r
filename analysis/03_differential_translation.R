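#!/usr/bin/env Rscript
# Differential translation by analysis of partial variance with RVM
# moderation, using the stringent reliability filters (slope p 0.05, band
# [-0.5, 1.5], |effect| >= 1 log2 on both scales) and the contrast-specific
# FDR cutoffs: 30% for the low-powered ex vivo comparison, 15% for the
# activated one. Single-fraction differential expression (polysome-only and
# cytosolic-only) is run alongside for comparison, as the translational
# calls should largely be invisible to the cytosolic analysis.

suppressPackageStartupMessages(library(polysomeAPV))
dir.create("results/apv", showWarnings = FALSE, recursive = TRUE)

contrasts <- list(
  exvivo = list(reference = "Tconv_ex", contrast = "Treg_ex", fdr = 0.30),
  activated = list(reference = "Tconv_act", contrast = "Treg_act",
                   fdr = 0.15))

for (nm in names(contrasts)) {
  ct <- contrasts[[nm]]
  ds <- align_paired_dataset(
    read_expression_tsv(sprintf("results/data/%s_cytosolic.tsv", nm)),
    read_expression_tsv(sprintf("results/data/%s_polysome.tsv", nm)),
    read_annotation_tsv(sprintf("results/data/%s_annotation.tsv", nm)))
  cfg <- apv_config(ct$reference, ct$contrast, fdr_threshold = ct$fdr)
  fit <- apv_analysis(ds, cfg)
  write_result_tsv(fit, sprintf("results/apv/%s_apv.tsv", nm))
  jsonlite::write_json(
    list(config = unclass(cfg), prior = unclass(fit$prior),
         counts = as.list(fit$counts)),
    sprintf("results/apv/%s_apv.json", nm),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf(
    "%s: %d/%d genes differentially translated at FDR %.0f%% (prior a=%.2f, b=%.2f); %d up, %d down",
    nm, fit$counts[["n_included"]], fit$counts[["n_complete"]],
    100 * ct$fdr, fit$prior$a, fit$prior$b,
    sum(fit$results$included & fit$results$delta_pt > 0),
    sum(fit$results$included & fit$results$delta_pt < 0)))

  truth <- read.delim(sprintf("results/data/%s_truth.tsv", nm))
  spiked <- truth$gene_id[truth$class != "transcriptional"]
  called <- fit$results$gene_id[fit$results$included]
  message(sprintf("   recovery: sensitivity %.2f, FDP %.2f",
                  length(intersect(called, spiked)) / length(spiked),
                  length(setdiff(called, spiked)) / max(1, length(called))))

  for (fr in c("polysome", "cytosolic")) {
    de <- de_analysis(ds[[fr]], ds$pairing$group, ct$reference,
                      ct$contrast, fdr_threshold = ct$fdr)
    write_result_tsv(de, sprintf("results/apv/%s_de_%s.tsv", nm, fr))
    message(sprintf("   %s-only DE: %d significant", fr,
                    de$counts[["n_significant"]]))
  }
}
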