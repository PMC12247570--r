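#!/usr/bin/env Rscript
# How forward-model similarity predicts recovery: for each single-region
# configuration under condition lc_0 (shared source dynamics, different
# forward models), correlate the mass-vs-field gain similarity of the EZ
# region with the evaluation metrics, binned in correlation intervals of
# width 0.1.  Requires 02 to have run.
#
# Usage: Rscript analysis/05_gain_similarity.R

library(vepres)

path <- file.path("results", "single_region", "reports.csv")
if (!file.exists(path)) stop("run analysis/02 first")
reports <- read.csv(path)
rec <- reports[reports$condition == "lc_0" & !is.na(reports$gain_r), ]
rec$r <- rec$gain_r

out <- file.path("results", "gain_similarity")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ca <- correlation_analysis(rec)
write.csv(ca$bins, file.path(out, "bins.csv"), row.names = FALSE)
cat("gain correlations of the EZ regions:",
    paste(round(sort(rec$r), 2), collapse = " "), "\n")
cat("Spearman rank correlation with each metric:\n")
print(round(ca$spearman, 3))
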