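#!/usr/bin/env Rscript
# Relative RNA amounts and condition-versus-glucose fold changes from the
# synthetic Ct table, recovering the programmed induction structure (hcd
# cluster ~1000x by 7-hydroxycoumarin and DHFP, ~100x by 7-methylcoumarin;
# xenA38 2-3x; xenA45 never detected).

suppressPackageStartupMessages(library(hcdkin))
dir.create("results", showWarnings = FALSE)

ct <- read.csv("results/ct_table.csv")
config <- scenario_config()

amounts <- summarize_replicates(ct)
write.csv(amounts, "results/qpcr_amounts.csv", row.names = FALSE)

folds <- config$inductions
folds$recovered <- mapply(function(g, cond) fold_change(ct, g, cond),
                          folds$gene, folds$condition)
write.csv(folds, "results/qpcr_folds.csv", row.names = FALSE)
message("Programmed vs recovered folds (replicate-mean, 16S reference):")
for (i in seq_len(nrow(folds)))
  message(sprintf("  %-7s %-18s %6g -> %8.1f", folds$gene[i],
                  folds$condition[i], folds$fold[i], folds$recovered[i]))
und <- amounts[amounts$gene %in% config$undetected_genes, ]
message(sprintf("xenA45 detected in %d of %d condition panels (expected 0)",
                sum(und$detected), nrow(und)))
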