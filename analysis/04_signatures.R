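#!/usr/bin/env Rscript
# Fold-change signatures and cross-dataset comparison. The activated
# translational signature uses a 3-fold threshold, the ex vivo one 2-fold.
# The activated signature is intersected with the secondary fold-change
# table (>= 1.3-fold), quadrant counts are tabulated, and sign concordance
# is tested with a one-sided binomial test against p = 1/2 — the
# concordant genes form the "secondary-axis-sensitive" module (in the
# motivating biology: the eIF4E-sensitive module).

suppressPackageStartupMessages(library(polysomeAPV))
dir.create("results/signatures", showWarnings = FALSE, recursive = TRUE)

folds <- c(exvivo = 2, activated = 3)
secondary <- read_effects_tsv("results/data/secondary_effects.tsv")

for (nm in names(folds)) {
  tab <- read.delim(sprintf("results/apv/%s_apv.tsv", nm))
  eff <- setNames(tab$delta_pt, tab$gene_id)
  sig <- build_signature(eff, tab$included, folds[[nm]], label = nm)
  writeLines(names(sig$up),
             sprintf("results/signatures/%s_up.txt", nm))
  writeLines(names(sig$down),
             sprintf("results/signatures/%s_down.txt", nm))
  message(sprintf("%s signature (>=%g-fold): %d up, %d down in Treg",
                  nm, folds[[nm]], length(sig$up), length(sig$down)))

  if (nm == "activated") {
    # how much of the translational signature is visible as a steady-state
    # (cytosolic) change of the same magnitude and direction? A low
    # percentage means the signature is invisible to conventional
    # steady-state profiling.
    de_c <- read.delim("results/apv/activated_de_cytosolic.tsv")
    steady <- setNames(de_c$effect, de_c$gene_id)
    ov <- overlap_percent(sig, steady, folds[[nm]], "same_direction")
    write.table(ov, "results/signatures/activated_overlap.tsv",
                sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("   shared with >=%g-fold steady-state changes: up %.1f%%, down %.1f%%",
                    folds[[nm]], ov$percent[1], ov$percent[2]))

    cm <- concordance_module(eff, tab$included, secondary,
                             secondary_fold = 1.3)
    jsonlite::write_json(
      list(quadrants = as.list(cm$quadrants),
           n_concordant = cm$n_concordant,
           n_discordant = cm$n_discordant,
           binomial_p = cm$binomial_p),
      "results/signatures/concordance.json",
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(cm$concordant_genes,
               "results/signatures/concordant_module.txt")
    message(sprintf("   concordance: %d concordant vs %d discordant, binomial p = %.3g",
                    cm$n_concordant, cm$n_discordant, cm$binomial_p))
  }
}
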