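#!/usr/bin/env Rscript
# Stage 5: conserved subnetworks between the two systems.
#
# Intersects the two inferred networks edge-for-edge, decomposes the
# conserved graph into connected components, annotates direction agreement
# (components whose genes move the same way in both systems), and scores
# recovery of the planted conserved modules with the regulator-restricted
# protocol (only TF-incident candidate pairs are scored against the
# regulator-to-target truth).

library(crossclr)

fx <- "scratch/fixtures"
net_a <- read_edge_list("results/network_vivo.tsv")
net_b <- read_edge_list("results/network_vitro.tsv")

de24 <- utils::read.delim("results/de_vivo_t24.tsv")
de48 <- utils::read.delim("results/de_vivo_t48.tsv")
dir_a <- ifelse(de24$direction == "none", de48$direction, de24$direction)
names(dir_a) <- de24$gene_id
de_b <- utils::read.delim("results/de_vitro.tsv")
dir_b <- stats::setNames(de_b$direction, de_b$gene_id)

cons <- intersect_networks(net_a, net_b, directions_a = dir_a,
                           directions_b = dir_b)
print(cons)
write_edge_list(cons$edges, "results/conserved_edges.tsv")
write_sif(cons$edges, "results/conserved_edges.sif")
write_graphml(cons$edges, "results/conserved_edges.graphml")

agree <- vapply(cons$components, function(cp)
  isTRUE(cp$direction_agreement), TRUE)
message(sum(agree), " of ", length(cons$components),
        " conserved components are direction-consistent in both systems")

truth <- utils::read.delim(file.path(fx, "truth_a.tsv"))
shared <- truth[truth$label == "shared", ]
rec <- score_network_recovery(cons$edges, shared,
                              regulators = readLines(file.path(fx, "tf_list.txt")))
message(sprintf("Planted conserved-module recovery: recall %.2f, precision %.2f (%d true edges)",
                rec$recall, rec$precision, rec$n_true))
utils::write.table(
  data.frame(metric = c("recall", "precision", "n_true", "n_conserved_tf_edges"),
             value = c(rec$recall, rec$precision, rec$n_true, rec$n_candidates)),
  "results/conserved_recovery.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
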