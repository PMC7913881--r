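#!/usr/bin/env Rscript
# Fit the ping-pong substrate-inhibition rate law to the synthetic velocity
# data, with identifiability diagnostics: bootstrap intervals, and the K_i
# profile on both designs (flat on the routine design, pinned by the
# extended inhibition series).

suppressPackageStartupMessages(library(hcdkin))
dir.create("results", showWarnings = FALSE)
seed <- 42
truth <- c(k_bim = 1490, k_nadph = 27, km_nadph_uM = 20, k_i_mM = 22)

d_ext <- read.csv("results/velocities_extended.csv")
d_std <- read.csv("results/velocities_routine.csv")

fit <- fit_rate_law(d_ext, e_total_nM = 99)
print(fit)
ci <- bootstrap_ci(d_ext, fit, n_boot = 200, seed = seed + 1)
est <- data.frame(parameter = names(fit$estimates),
                  truth = unname(truth),
                  estimate = unname(fit$estimates),
                  se = unname(fit$se),
                  ci_lower = ci$lower, ci_upper = ci$upper)
write.csv(est, "results/fit_estimates.csv", row.names = FALSE)
message(sprintf("Recovery errors: %s",
                paste(sprintf("%s %+0.1f%%", names(truth),
                              100 * (fit$estimates / truth - 1)),
                      collapse = ", ")))

grid <- 10^seq(log10(2), log10(1000), length.out = 15)
prof_ext <- profile_likelihood(d_ext, fit, "k_i_mM", grid)
fit_std <- fit_rate_law(d_std, e_total_nM = 99)
prof_std <- profile_likelihood(d_std, fit_std, "k_i_mM", grid)
prof <- rbind(cbind(design = "extended", prof_ext),
              cbind(design = "routine", prof_std))
write.csv(prof, "results/ki_profile.csv", row.names = FALSE)
message(sprintf("K_i profile: extended design has its minimum near %.0f mM; ",
                prof_ext$value[which.min(prof_ext$objective)]),
        sprintf("routine design is monotone-flat (identifiable: %s)",
                fit_std$k_i_identifiable))
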