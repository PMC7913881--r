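#!/usr/bin/env Rscript
# Verify the pathway ion assignments and the conversion-yield stoichiometry:
# nominal [M-H]-/[M+H]+ adduct masses for the compound registry, matches for
# the four observed ions, and the theoretical yield of
# 3-(2,4-dihydroxyphenyl)propionic acid from 59 mg of 7-hydroxycoumarin.

suppressPackageStartupMessages(library(hcdkin))
dir.create("results", showWarnings = FALSE)

reg <- pathway_registry()
reg$mz_neg_nominal <- vapply(reg$formula, adduct_mz, numeric(1),
                             adduct = "[M-H]-")
reg$mz_pos_nominal <- vapply(reg$formula, adduct_mz, numeric(1),
                             adduct = "[M+H]+")
reg$mz_neg_mono <- vapply(reg$formula, adduct_mz, numeric(1),
                          adduct = "[M-H]-", mass_kind = "monoisotopic")
write.csv(reg, "results/pathway_registry_mz.csv", row.names = FALSE)

observed <- data.frame(mz = c(161, 163, 181, 212),
                       polarity = c("-", "-", "-", "+"))
assign <- match_ions(observed)
write.csv(assign, "results/ion_assignments.csv", row.names = FALSE)
message("Observed-ion assignments:")
for (i in seq_len(nrow(assign)))
  message(sprintf("  m/z %g (%s) -> %s", assign$mz[i], assign$polarity[i],
                  assign$compound[i]))

y <- theoretical_yield(59, "C9H6O3", "C9H10O4", actual_mg = 50)
message(sprintf(
  "Yield: 59 mg 7-hydroxycoumarin (MW %.2f) -> theoretical %.1f mg acid %s",
  y$mw_in, y$theoretical_mg,
  sprintf("(MW %.2f); 50 mg isolated = %.1f%% of theoretical",
          y$mw_out, y$percent_of_theoretical)))
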