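#!/usr/bin/env Rscript
# Stage 2: preprocessing and differential expression in both systems.
#
# In vivo: floor at 5.0, per-chip 50th-percentile and per-gene median
# normalization, present-flag (>= 50%) and sample-correlation (mean r >= 0.8)
# QC, log2; then one-way ANOVA across the 5 dose groups at each time point
# with p < 0.05 and a max-pairwise 1.5-fold filter, unioned over time
# points. In vitro: same preprocessing, then an unpaired t-test (p < 0.05,
# 1.5-fold) of treated vs control. The two gene lists are intersected into
# a Venn partition.

library(crossclr)

fx <- "scratch/fixtures"
dir.create("results", showWarnings = FALSE)

vivo <- read_expression_matrix(file.path(fx, "vivo_matrix.tsv"),
                               file.path(fx, "vivo_flags.tsv"))
vivo_design <- read_study_design(file.path(fx, "vivo_design.tsv"))
norm_a <- normalize_pipeline(vivo)
message("In vivo: kept ", norm_a$n_genes_kept, "/", norm_a$n_genes_in,
        " genes; excluded samples: ",
        if (length(norm_a$excluded_samples)) paste(norm_a$excluded_samples, collapse = ", ") else "none")

de_a <- anova_dose_filter_union(norm_a$matrix, vivo_design)
for (t in names(de_a$per_time))
  utils::write.table(de_a$per_time[[t]],
                     file.path("results", paste0("de_vivo_", t, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
message("In vivo DE (union over time points): ", length(de_a$genes), " genes")

vitro <- read_expression_matrix(file.path(fx, "vitro_matrix.tsv"),
                                file.path(fx, "vitro_flags.tsv"))
vitro_design <- read_study_design(file.path(fx, "vitro_design.tsv"))
norm_b <- normalize_pipeline(vitro)
de_b <- ttest_filter(norm_b$matrix, vitro_design)
utils::write.table(de_b, "results/de_vitro.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("In vitro DE: ", sum(de_b$passes), " genes")

venn <- intersect_gene_lists(de_a$genes, de_b$gene_id[de_b$passes])
message("Common DE genes: ", venn$counts[["common"]],
        " (in vivo only ", venn$counts[["a_only"]],
        ", in vitro only ", venn$counts[["b_only"]], ")")
writeLines(venn$common, "results/common_genes.txt")
utils::write.table(
  data.frame(block = names(venn$counts), count = as.integer(venn$counts)),
  "results/venn_counts.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
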