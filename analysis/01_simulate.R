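#!/usr/bin/env Rscript
# Generate every synthetic input the pipeline consumes: the initial-velocity
# grid (routine and extended-inhibition designs), NADPH-depletion absorbance
# traces at the standard assay condition, and the triplicate qPCR Ct table.

suppressPackageStartupMessages(library(hcdkin))
dir.create("results", showWarnings = FALSE)
seed <- 42

truth <- kinetic_params(99, 1490, 27, 20, 22)
message("Generating truth: k_bim 1490 mM^-1 s^-1, k_NADPH 27 s^-1, ",
        "Km_NADPH 20 uM, K_i 22 mM at 99 nM enzyme")

d_std <- generate_velocity_dataset(velocity_design(), truth, seed = seed)
d_ext <- generate_velocity_dataset(velocity_design(extended = TRUE), truth,
                                   seed = seed)
write.csv(d_std, "results/velocities_routine.csv", row.names = FALSE)
write.csv(d_ext, "results/velocities_extended.csv", row.names = FALSE)
message(sprintf("Velocity datasets: %d routine rows (7HK <= 150 uM), %d ",
                nrow(d_std), nrow(d_ext)),
        "extended rows (7HK to 60 mM; the inhibition series)")

traces <- generate_absorbance_traces(truth, seed = seed)
flat <- do.call(rbind, lapply(seq_along(traces), function(i)
  cbind(replicate = i, traces[[i]])))
write.csv(flat, "results/a365_traces.csv", row.names = FALSE)
message(sprintf("Absorbance traces: %d replicates x %d points at 365 nm ",
                length(traces), nrow(traces[[1]])),
        "(160 uM NADPH, 60 uM 7HK)")

ct <- generate_ct_table(scenario_config(), seed = seed)
write.csv(ct, "results/ct_table.csv", row.names = FALSE)
message(sprintf("Ct table: %d rows (%d genes x %d conditions, triplicate, ",
                nrow(ct), length(unique(ct$gene)),
                length(unique(ct$condition))),
        "16S reference)")
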