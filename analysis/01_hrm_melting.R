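#!/usr/bin/env Rscript
# HRM melting analysis of cytosine-modified templates.
#
# Simulates SYBR-green melting curves for all five cytosine species on the
# instrument ramp (50-90 C, 0.1 C steps), calls Tm from the smoothed negative
# derivative, and contrasts modification groups. The headline observation:
# methylated templates melt highest, hydroxymethylated lowest -
# Tm(5mC) > Tm(C) > Tm(5hmC), with 5fC the least stable overall.

suppressMessages(library(modkin))
seed <- 101
dir.create("results", showWarnings = FALSE)

labels <- modification_labels()
sim <- make_melt_curves(labels, n_replicates = 4, noise_sd = 0.01, seed = seed)

per_label <- hrm_call_tms(sim$curves)                 # replicate-averaged
per_curve <- hrm_call_tms(sim$curves, by = "curve")   # for group tests
cmp <- compare_tm_groups(split(per_curve$tm_C, per_curve$label))

write.csv(per_curve, "results/hrm_tm_calls.csv", row.names = FALSE)
write.csv(cmp, "results/hrm_group_comparison.csv", row.names = FALSE)

cat("Called Tm per label (replicate-averaged, degrees C):\n")
print(per_label[order(-per_label$tm_C), c("label", "tm_C", "peak_height")],
      row.names = FALSE)
tm <- function(l) per_label$tm_C[per_label$label == l]
cat(sprintf("\nTm(5mC) - Tm(C)  = %+.2f C\nTm(5hmC) - Tm(C) = %+.2f C\n",
            tm("5mC") - tm("C"), tm("5hmC") - tm("C")))
cat(sprintf("Stability ordering 5mC > C > 5hmC holds: %s\n",
            tm("5mC") > tm("C") && tm("C") > tm("5hmC")))
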