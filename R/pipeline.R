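#' Default analysis thresholds
#'
#' One block holding every threshold of the comparison workflow: intensity
#' floor 5.0, present-call fraction 0.5, sample QC mean correlation 0.8,
#' DE alpha 0.05 and 1.5-fold filter, CLR with 10 bins, spline order 3 and
#' composite cutoff 2.0, TF hub threshold 15.
#'
#' @param ... overrides for individual entries.
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(...) {
  utils::modifyList(
    list(floor = 5.0, present_fraction = 0.5, qc_min_r = 0.8,
         alpha = 0.05, fold = 1.5,
         n_bins = 10L, spline_order = 3L, z_cutoff = 2.0,
         tf_min_connections = 15L),
    list(...))
}

#' Run the full cross-system comparison workflow
#'
#' Executes the complete chain: normalize both systems' perturbation
#' datasets, call differential expression (dose-series ANOVA for system A,
#' unpaired t-test for system B), intersect the gene lists, cluster the
#' control-normalized condition averages, infer a CLR network per system on
#' the common genes using the compendium samples, intersect the networks
#' into conserved subnetworks, and tabulate TF connectivity. Gene lists for
#' the networks and the samples they are scored on come from different
#' inputs on purpose: the DE datasets choose the genes, the compendia supply
#' the expression.
#'
#' @param config a list with entries:
#'   \describe{
#'     \item{system_a}{list(de_matrix, de_design, compendium_matrix,
#'       compendium_design) — `ExpressionMatrix` objects and design frames.
#'       The DE matrix must be intensity scale (the chain normalizes it).}
#'     \item{system_b}{same, with a control/treated DE design.}
#'     \item{tf_ids}{character vector of transcription-factor ids.}
#'     \item{thresholds}{optional, see [default_thresholds()].}
#'   }
#' @param out_dir optional directory; when given, stage outputs (edge lists,
#'   Newick trees, TSV tables) and the manifest are written there.
#' @return A list with all stage outputs plus `manifest` (config snapshot,
#'   per-stage counts, seed-free determinism record).
#' @export
run_full_comparison <- function(config, out_dir = NULL) {
  for (nm in c("system_a", "system_b", "tf_ids"))
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")
  for (sys in c("system_a", "system_b"))
    for (nm in c("de_matrix", "de_design", "compendium_matrix",
                 "compendium_design"))
      if (is.null(config[[sys]][[nm]]))
        stop("config$", sys, " is missing '", nm, "'")
  th <- do.call(default_thresholds, as.list(config$thresholds))
  counts <- list()

  norm_a <- normalize_pipeline(config$system_a$de_matrix, floor = th$floor,
                               min_fraction = th$present_fraction,
                               min_mean_r = th$qc_min_r)
  norm_b <- normalize_pipeline(config$system_b$de_matrix, floor = th$floor,
                               min_fraction = th$present_fraction,
                               min_mean_r = th$qc_min_r)
  counts$genes_after_qc_a <- nrow(norm_a$matrix$values)
  counts$genes_after_qc_b <- nrow(norm_b$matrix$values)

  de_a <- anova_dose_filter_union(norm_a$matrix, config$system_a$de_design,
                                  alpha = th$alpha, fold = th$fold)
  de_b <- ttest_filter(norm_b$matrix, config$system_b$de_design,
                       alpha = th$alpha, fold = th$fold)
  genes_a <- de_a$genes
  genes_b <- de_b$gene_id[de_b$passes]
  venn <- intersect_gene_lists(genes_a, genes_b)
  counts$de_a <- length(genes_a)
  counts$de_b <- length(genes_b)
  counts$common <- length(venn$common)

  # cluster control-normalized condition averages of the common genes
  cluster_cond <- NULL
  if (length(venn$common) >= 3L) {
    ratio_a <- control_ratio_matrix(
      floor_intensities(config$system_a$de_matrix, th$floor),
      config$system_a$de_design)
    ratio_b <- control_ratio_matrix(
      floor_intensities(config$system_b$de_matrix, th$floor),
      config$system_b$de_design)
    avg_a <- average_replicates(em_subset(ratio_a,
      genes = match(venn$common, gene_ids(ratio_a))),
      config$system_a$de_design)
    avg_b <- average_replicates(em_subset(ratio_b,
      genes = match(venn$common, gene_ids(ratio_b))),
      config$system_b$de_design)
    combined <- expression_matrix(
      log2(cbind(avg_a$values, avg_b$values)), scale = "log2")
    cluster_cond <- two_way_cluster(combined)
  }

  params <- clr_params(n_bins = th$n_bins, spline_order = th$spline_order,
                       z_cutoff = th$z_cutoff)
  net_for <- function(sys) {
    comp <- sys$compendium_matrix
    keep <- match(intersect(venn$common, gene_ids(comp)), gene_ids(comp))
    if (length(keep) < 3L) stop("fewer than 3 common genes in the compendium")
    sub <- em_subset(comp, genes = keep)
    if (sub$scale == "intensity") sub <- log2_transform(floor_intensities(sub, th$floor))
    threshold_network(clr_scores(mi_matrix(sub, params), params))
  }
  net_a <- net_for(config$system_a)
  net_b <- net_for(config$system_b)
  counts$net_a <- c(nodes = length(net_a$nodes), edges = nrow(net_a$edges))
  counts$net_b <- c(nodes = length(net_b$nodes), edges = nrow(net_b$edges))

  dir_a <- stats::setNames(de_a$per_time[[1L]]$direction,
                           de_a$per_time[[1L]]$gene_id)
  dir_b <- stats::setNames(de_b$direction, de_b$gene_id)
  conserved <- intersect_networks(net_a, net_b,
                                  directions_a = dir_a, directions_b = dir_b)
  counts$conserved_edges <- nrow(conserved$edges)
  counts$conserved_components <- length(conserved$components)

  tf_a <- tf_degree_table(net_a, config$tf_ids, th$tf_min_connections)
  tf_b <- tf_degree_table(net_b, config$tf_ids, th$tf_min_connections)
  tf_ratio <- degree_ratio_flags(
    stats::setNames(tf_a$degree, tf_a$tf),
    stats::setNames(tf_b$degree, tf_b$tf))

  manifest <- list(
    package_version = as.character(utils::packageVersion("crossclr")),
    thresholds = th, counts = counts,
    excluded_samples = list(a = norm_a$excluded_samples,
                            b = norm_b$excluded_samples))
  result <- list(normalized = list(a = norm_a, b = norm_b),
                 de = list(a = de_a, b = de_b), venn = venn,
                 clusters = cluster_cond,
                 networks = list(a = net_a, b = net_b),
                 conserved = conserved,
                 tf_degrees = list(a = tf_a, b = tf_b, ratio = tf_ratio),
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_edge_list(net_a, file.path(out_dir, "network_a.tsv"))
    write_edge_list(net_b, file.path(out_dir, "network_b.tsv"))
    write_edge_list(conserved$edges, file.path(out_dir, "conserved_edges.tsv"))
    write_sif(conserved$edges, file.path(out_dir, "conserved_edges.sif"))
    if (!is.null(cluster_cond))
      write_newick(cluster_cond$conditions,
                   file.path(out_dir, "conditions.nwk"))
    utils::write.table(tf_a, file.path(out_dir, "tf_degrees_a.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tf_b, file.path(out_dir, "tf_degrees_b.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$checksums <- tools::md5sum(files)
    result$manifest <- manifest
  }
  result
}
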