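#!/usr/bin/env Rscript
# DNA fiber combing: replication fork speed in two genotypes.
#
# Simulates dual-pulse (IdU -> CldU) fiber tracks for a wild-type-like
# population (mean 1.5 kb/min) and a hypomethylated population with a 10%
# faster mean (the direction reported for DNA lacking 5mC), classifies
# tracks, converts CldU lengths to fork speed (1 um = 2 kb, 15 min pulse)
# and contrasts the distributions with a Mann-Whitney test.

suppressMessages(library(modkin))
seed <- 404
dir.create("results", showWarnings = FALSE)

wt <- make_fiber_set(300, speed_mean_kb_per_min = 1.5, speed_sd = 0.3,
                     seed = seed)
tko <- make_fiber_set(300, speed_mean_kb_per_min = 1.65, speed_sd = 0.3,
                      seed = seed + 1)
sp_wt <- fiber_speeds(wt$tracks)
sp_tko <- fiber_speeds(tko$tracks)
res <- summarize_rfs(list(wt = sp_wt, tko = sp_tko))

speeds <- rbind(cbind(genotype = "wt", sp_wt), cbind(genotype = "tko", sp_tko))
write.csv(speeds, "results/rfs_speeds.csv", row.names = FALSE)
write.csv(res$summary, "results/rfs_summary.csv", row.names = FALSE)
write.csv(res$tests, "results/rfs_tests.csv", row.names = FALSE)

cat("Track pattern census (wt):\n"); print(table(sp_wt$pattern))
cat("\nFork speed summary (kb/min):\n"); print(res$summary, row.names = FALSE)
cat(sprintf("\nwt vs tko: median shift %.3f kb/min, Mann-Whitney p = %.3g\n",
            -res$tests$delta_median, res$tests$p_value))
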