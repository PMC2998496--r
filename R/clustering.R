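#' Normalize each sample by its stratum's control means
#'
#' Within each (system, time point) stratum, every sample is divided,
#' gene-wise, by the mean of that gene over the stratum's control samples,
#' turning values into treated/control ratios on a common baseline.
#'
#' @param m an `ExpressionMatrix` on intensity or ratio scale (positive
#'   control means required).
#' @param design design table covering the samples.
#' @param strata design columns defining the control stratum (default
#'   system and time point).
#' @return An `ExpressionMatrix` on ratio scale.
#' @export
control_ratio_matrix <- function(m, design, strata = c("system", "time_h")) {
  design <- match_design(m, design)
  key <- interaction(design[strata], drop = TRUE)
  out <- m$values
  for (s in levels(key)) {
    cols <- which(key == s)
    ctrl <- cols[design$is_control[cols]]
    if (!length(ctrl))
      stop("stratum '", s, "' has no control samples")
    ctrl_mean <- rowMeans(m$values[, ctrl, drop = FALSE])
    if (any(ctrl_mean <= 0))
      stop("non-positive control mean in stratum '", s, "'")
    out[, cols] <- m$values[, cols, drop = FALSE] / ctrl_mean
  }
  expression_matrix(out, scale = "ratio", flags = m$flags)
}

#' Average replicate samples into one column per condition
#'
#' Conditions are keyed by (system, compound, dose, time point); replicate
#' columns are averaged arithmetically and the output column names encode
#' the condition key as `system|compound|dose|time_h`.
#'
#' @param m an `ExpressionMatrix`.
#' @param design design table covering the samples.
#' @return An `ExpressionMatrix` with one column per condition (same scale).
#' @export
average_replicates <- function(m, design) {
  design <- match_design(m, design)
  key <- paste(design$system, design$compound, design$dose, design$time_h,
               sep = "|")
  levels_in_order <- unique(key)
  cols <- lapply(levels_in_order, function(k)
    rowMeans(m$values[, key == k, drop = FALSE]))
  out <- do.call(cbind, cols)
  colnames(out) <- levels_in_order
  rownames(out) <- gene_ids(m)
  expression_matrix(out, scale = m$scale)
}

#' Pearson correlation distance
#'
#' `d = 1 - r`, in `[0, 2]`: identical profiles are at distance 0, exactly
#' anti-correlated profiles at distance 2.
#'
#' @param a,b numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation distance.
#' @export
pearson_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance input; correlation undefined")
  1 - stats::cor(a, b)
}

#' Pairwise Pearson-distance matrix
#'
#' @param m an `ExpressionMatrix`.
#' @param axis `"samples"` (distance between columns) or `"genes"` (rows).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
pearson_dissimilarity <- function(m, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  v <- if (axis == "samples") m$values else t(m$values)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance profile: ", colnames(v)[which(sds == 0)[1L]])
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the pair of clusters with the smallest mean pairwise
#' dissimilarity at every step. Ties are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' member), which makes the tree deterministic across platforms.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal and
#'   row/column names as leaf labels.
#' @return An object of class `hclust` (method `"average"`), usable with
#'   [stats::cutree()], [ape::as.phylo()] etc.
#' @export
average_linkage_cluster <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("'d' must be a square matrix")
  if (any(abs(d - t(d)) > 1e-12)) stop("'d' must be symmetric")
  if (any(diag(d) != 0)) stop("'d' must have a zero diagonal")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters: list of member leaf indices; id: negative leaf index or
  # positive merge step (hclust convention)
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  # label of a cluster = its lexicographically smallest leaf label
  clabel <- labels
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- D[i, j]
      lab <- sort(c(clabel[i], clabel[j]))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (lab[1L] < best$lab[1L] ||
            (lab[1L] == best$lab[1L] && lab[2L] < best$lab[2L])))) {
        best <- list(i = i, j = j, d = dij, lab = lab)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best$d
    # UPGMA update: size-weighted average of distances
    newrow <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    clabel <- c(clabel[keep], min(clabel[c(i, j)]))
  }
  order <- hclust_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 dist.method = "custom", call = match.call()),
            class = "hclust")
}

# leaf order by left-to-right traversal of the merge tree
hclust_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Two-way hierarchical clustering of an expression matrix
#'
#' Clusters both genes (rows) and conditions (columns) with Pearson distance
#' and average linkage; the two axes are independent.
#'
#' @param m an `ExpressionMatrix` (typically control-ratio, condition-
#'   averaged, log2 values).
#' @return A list with `genes` and `conditions`, each an `hclust`.
#' @export
two_way_cluster <- function(m) {
  list(genes = average_linkage_cluster(pearson_dissimilarity(m, "genes")),
       conditions = average_linkage_cluster(pearson_dissimilarity(m, "samples")))
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths via [ape::as.phylo()]; labels are
#' quoted so condition keys containing `|` survive round trips.
#'
#' @param h an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(h, path) {
  phy <- ape::as.phylo(h)
  ape::write.tree(phy, file = path)
  invisible(path)
}
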