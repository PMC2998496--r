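#!/usr/bin/env Rscript
# Stage 3: two-way hierarchical clustering of the common genes.
#
# Each sample is normalized by the mean of its stratum's control samples
# (per gene), replicates are averaged into one column per condition, and
# genes x conditions are clustered with Pearson distance / average linkage.
# The condition tree shows how in vitro treatment co-clusters with the
# high-dose in vivo conditions.

library(crossclr)

fx <- "scratch/fixtures"
common <- readLines("results/common_genes.txt")

load_ratio <- function(stem) {
  m <- read_expression_matrix(file.path(fx, paste0(stem, "_matrix.tsv")),
                              file.path(fx, paste0(stem, "_flags.tsv")))
  design <- read_study_design(file.path(fx, paste0(stem, "_design.tsv")))
  r <- control_ratio_matrix(floor_intensities(m), design)
  average_replicates(
    expression_matrix(r$values[common, , drop = FALSE], "ratio"), design)
}

avg_vivo <- load_ratio("vivo")
avg_vitro <- load_ratio("vitro")
combined <- expression_matrix(log2(cbind(avg_vivo$values, avg_vitro$values)),
                              scale = "log2")
message("Clustering ", nrow(combined$values), " genes x ",
        ncol(combined$values), " conditions")

tw <- two_way_cluster(combined)
write_newick(tw$conditions, "results/conditions.nwk")
write_newick(tw$genes, "results/genes.nwk")

ord <- tw$conditions$labels[tw$conditions$order]
message("Condition leaf order:\n  ", paste(ord, collapse = "\n  "))
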