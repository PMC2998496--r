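#!/usr/bin/env Rscript
# Stage 4: CLR network inference per system.
#
# The gene list comes from the common DE genes (stage 2); the expression
# comes from each system's multi-compound compendium — deliberately
# different inputs, because a static regulatory network needs heterogeneous
# conditions while the DE filter needs a focused perturbation design. CLR
# scores every gene pair by B-spline mutual information (10 bins, spline
# order 3) standardized against both genes' background MI distributions;
# edges with composite z >= 2.0 are retained. TF connectivity is tabulated
# per network.

library(crossclr)

fx <- "scratch/fixtures"
common <- readLines("results/common_genes.txt")
tfs <- readLines(file.path(fx, "tf_list.txt"))
params <- clr_params(n_bins = 10, spline_order = 3, z_cutoff = 2.0)

infer <- function(stem) {
  m <- read_expression_matrix(file.path(fx, paste0(stem, "_matrix.tsv")),
                              file.path(fx, paste0(stem, "_flags.tsv")))
  m <- log2_transform(floor_intensities(m))
  keep <- intersect(common, gene_ids(m))
  sub <- expression_matrix(m$values[keep, , drop = FALSE], "log2")
  net <- threshold_network(clr_scores(mi_matrix(sub, params), params))
  message(stem, ": ", length(net$nodes), " nodes, ", nrow(net$edges),
          " edges at cutoff ", params$z_cutoff)
  net
}

net_a <- infer("compendium_a")
net_b <- infer("compendium_b")
write_edge_list(net_a, "results/network_vivo.tsv")
write_edge_list(net_b, "results/network_vitro.tsv")
write_sif(net_a, "results/network_vivo.sif")
write_sif(net_b, "results/network_vitro.sif")

tf_a <- tf_degree_table(net_a, tfs)
tf_b <- tf_degree_table(net_b, tfs)
ratio <- degree_ratio_flags(stats::setNames(tf_a$degree, tf_a$tf),
                            stats::setNames(tf_b$degree, tf_b$tf))
utils::write.table(tf_a, "results/tf_degrees_vivo.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(tf_b, "results/tf_degrees_vitro.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(ratio, "results/tf_degree_ratio.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("TF hubs (> 15 connections) in vivo: ",
        paste(tf_a$tf[tf_a$highlight], collapse = ", "))
message("TFs with >= 2x asymmetric connectivity: ",
        paste(ratio$tf[ratio$flagged], collapse = ", "))
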