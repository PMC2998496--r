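#!/usr/bin/env Rscript
# Stage 6: gene-set over-representation of the common DE genes.
#
# A transparent hypergeometric test against user-supplied GMT gene sets
# stands in for proprietary knowledge-base tools. Here the gene sets are the
# planted regulons (one set per TF module), so conserved modules should
# light up while system-specific and random sets should not.

library(crossclr)

fx <- "scratch/fixtures"
truth_a <- utils::read.delim(file.path(fx, "truth_a.tsv"))
universe <- gene_ids(read_expression_matrix(file.path(fx, "vivo_matrix.tsv")))

sets <- lapply(split(truth_a$target, truth_a$regulator),
               function(tg) unique(tg))
set.seed(1)
sets$random_set <- sample(universe, 12)
gmt <- "results/modules.gmt"
write_gmt(sets, gmt, description = c(rep("planted regulon", length(sets) - 1),
                                     "random control set"))

common <- readLines("results/common_genes.txt")
res <- hypergeometric_enrichment(common, read_gmt(gmt), universe)
utils::write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("Significant sets (p < 0.05): ",
        paste(res$set[res$significant], collapse = ", "))
print(res, digits = 3)
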