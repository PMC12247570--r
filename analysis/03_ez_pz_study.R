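#!/usr/bin/env Rscript
# Configurations with a propagation zone: one-region EZ plus one-to-two
# mesh-adjacent PZ regions, with the global coupling adjusted per
# configuration so the PZ (and only the PZ) is recruited.  Simulated in the
# control condition and inverted as in the single-region study.
#
# Usage: Rscript analysis/03_ez_pz_study.R [seed]

library(vepres)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- file.path("results", "ez_pz")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- experiment_config(seed = seed, n_single = 0, n_ezpz = 5,
                         conditions = "lc_none", n_seeds = 50)
study <- run_catalogue(cfg, out_dir = file.path(out, "cells"),
                       progress = TRUE)
write.csv(study$reports, file.path(out, "reports.csv"), row.names = FALSE)
cat(sprintf("adjusted couplings: %s\n",
            paste(round(study$reports$gc, 2), collapse = " ")))
cat(sprintf("median F1 %.2f, median GOF %.2f over %d configurations\n",
            median(study$reports$f1), median(study$reports$gof),
            nrow(study$reports)))
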