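#!/usr/bin/env Rscript
# Gene-set over-representation within the direction-split differential
# calls of the activated contrast, for all three views of the data
# (cytosol-corrected translation, polysome-only DE, cytosolic-only DE).
# Terms are reported when they pass the stringent filters: >2-fold
# enrichment, >=10 regulated+annotated genes, FDR < 1%. The -log10
# adjusted-p comparison matrix is floored at p = 1e-7.

suppressPackageStartupMessages(library(polysomeAPV))
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

apv <- read.delim("results/apv/activated_apv.tsv")
universe <- apv$gene_id
# GMT files carry no universe; the eligible universe is every gene on the
# analysed matrix
collection <- read_gmt("results/data/gene_sets.gmt", universe = universe)

sets <- list(
  translation_up = apv$gene_id[apv$included & apv$delta_pt > 0],
  translation_down = apv$gene_id[apv$included & apv$delta_pt < 0])
for (fr in c("polysome", "cytosolic")) {
  de <- read.delim(sprintf("results/apv/activated_de_%s.tsv", fr))
  sets[[paste0(fr, "_up")]] <- de$gene_id[de$significant & de$effect > 0]
  sets[[paste0(fr, "_down")]] <- de$gene_id[de$significant & de$effect < 0]
}

for (lab in names(sets)) {
  tab <- enrich(sets[[lab]], collection, universe = universe)
  write.table(tab, sprintf("results/enrichment/%s.tsv", lab),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pass <- tab[tab$passes_filters, ]
  message(sprintf("%s (%d genes): %d/%d terms pass filters%s",
                  lab, length(sets[[lab]]), nrow(pass), nrow(tab),
                  if (nrow(pass) > 0)
                    paste0(" (", paste(pass$term_id, collapse = ", "), ")")
                  else ""))
}

hm <- enrichment_compare(sets, collection, universe = universe)
write.table(data.frame(term_id = rownames(hm), hm, check.names = FALSE),
            "results/enrichment/minus_log10_fdr_matrix.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("comparison matrix written (values capped at 7 = -log10 1e-7)")
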