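#!/usr/bin/env Rscript
# Build the synthetic brain used throughout the study and write its
# artifacts: cortical mesh (PLY + per-vertex normals/areas), parcellation,
# connectome, depth-electrode contacts, and the region sampling scores of
# the implantation.
#
# Usage: Rscript analysis/01_build_geometry.R [seed]

library(vepres)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- file.path("results", "geometry")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

geom <- build_geometry(seed = derive_seed(seed, "geometry"))
cat(sprintf("mesh: %d vertices, %d triangles, mean edge %.2f mm\n",
            nrow(geom$mesh$vertices), nrow(geom$mesh$triangles),
            mesh_mean_edge_length(geom$mesh)))
cat(sprintf("parcellation: %d cortical regions (%d-%d vertices), %d subcortical nodes\n",
            geom$parcellation$n_regions,
            min(tabulate(geom$parcellation$region_label)),
            max(tabulate(geom$parcellation$region_label)),
            nrow(geom$parcellation$subcortical)))

write_mesh_ply(geom$mesh, file.path(out, "cortex.ply"))
write.table(data.frame(vertex = seq_along(geom$parcellation$region_label),
                       region = geom$parcellation$region_label),
            file.path(out, "parcellation.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write_connectome_csv(geom$connectome, file.path(out, "connectome.csv"))
write_contacts_tsv(geom$sensors, file.path(out, "contacts.tsv"))

gains <- prepare_gains(geom)
score <- apply(abs(gains$nmm_bip$g[, seq_len(geom$parcellation$n_regions)]),
               2, max)
write.csv(data.frame(region = seq_along(score), sampling_score = score),
          file.path(out, "sampling_scores.csv"), row.names = FALSE)
cat("best-implanted regions:",
    paste(order(score, decreasing = TRUE)[1:8], collapse = " "), "\n")
cat("artifacts written under", out, "\n")
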