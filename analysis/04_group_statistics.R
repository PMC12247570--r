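#!/usr/bin/env Rscript
# Group-level statistics over the completed studies: per-condition medians
# of the four evaluation metrics, Kruskal-Wallis tests across the four
# conditions, and paired Wilcoxon signed-rank tests of the control condition
# against each field condition.  Requires 02 (and optionally 03) to have run.
#
# Usage: Rscript analysis/04_group_statistics.R

library(vepres)

paths <- c(file.path("results", "single_region", "reports.csv"),
           file.path("results", "ez_pz", "reports.csv"))
paths <- paths[file.exists(paths)]
if (length(paths) == 0) stop("run analysis/02 (and 03) first")
reports <- do.call(rbind, lapply(paths, read.csv))

out <- file.path("results", "group")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
gs <- group_stats(reports)
for (ct in names(gs)) {
  cat("==", ct, "\n")
  print(round(gs[[ct]]$medians, 3))
  cat("Kruskal-Wallis p:", format(gs[[ct]]$kruskal_p, digits = 3), "\n")
  if (!all(is.na(gs[[ct]]$wilcoxon_p))) {
    cat("paired Wilcoxon vs lc_none:\n")
    print(signif(gs[[ct]]$wilcoxon_p, 3))
  }
  write.csv(gs[[ct]]$medians, file.path(out, paste0(ct, "_medians.csv")))
}
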