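#' CLR inference parameters
#'
#' Parameters of the context-likelihood-of-relatedness pipeline: the number
#' of B-spline bins, the spline order (an order-3 spline corresponds to the
#' commonly quoted "spline degree of 3"; order 1 degenerates to hard
#' binning), the composite z-score cutoff, the mutual-information log base,
#' and whether negative background z-scores are clamped to zero before
#' squaring (the original CLR behaviour, which stops mutually-low-MI pairs
#' from scoring high).
#'
#' @param n_bins number of bins (>= spline_order).
#' @param spline_order B-spline order (>= 1).
#' @param z_cutoff composite score threshold (inclusive, >= 0).
#' @param log_base 2 for MI in bits, `exp(1)` for nats.
#' @param z_clamp clamp negative z to 0 (default TRUE).
#' @return A list of class `clr_params`.
#' @export
clr_params <- function(n_bins = 10L, spline_order = 3L, z_cutoff = 2.0,
                       log_base = 2, z_clamp = TRUE) {
  if (spline_order < 1L) stop("spline_order must be >= 1")
  if (n_bins < spline_order) stop("n_bins must be >= spline_order")
  if (z_cutoff < 0) stop("z_cutoff must be >= 0")
  structure(list(n_bins = as.integer(n_bins),
                 spline_order = as.integer(spline_order),
                 z_cutoff = z_cutoff, log_base = log_base,
                 z_clamp = isTRUE(z_clamp)),
            class = "clr_params")
}

#' B-spline bin membership weights
#'
#' Soft discretization: each value is linearly rescaled from its range onto
#' the spline domain and evaluated against `n_bins` B-spline basis functions
#' on a uniform knot vector with order-fold repeated boundary knots. Every
#' row of the result is nonnegative and sums to 1 (partition of unity);
#' order 1 reproduces equal-width hard binning.
#'
#' @param x numeric vector (length >= 2, finite).
#' @param n_bins number of bins.
#' @param spline_order spline order (1 = indicator bins, 3 = quadratic).
#' @return A `length(x) x n_bins` weight matrix, or `NULL` when `x` is
#'   constant (degenerate input; callers treat its MI as 0).
#' @export
bspline_weights <- function(x, n_bins = 10L, spline_order = 3L) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (any(!is.finite(x))) stop("values must be finite")
  if (n_bins < spline_order) stop("n_bins must be >= spline_order")
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(NULL)
  top <- n_bins - spline_order + 1L
  z <- (x - rng[1L]) / (rng[2L] - rng[1L]) * top
  knots <- c(rep(0, spline_order), seq_len(top - 1L), rep(top, spline_order))
  splines::splineDesign(knots, z, ord = spline_order)
}

# internal: entropy of a probability vector, in the configured base
plugin_entropy <- function(p, log_base) {
  p <- p[p > 0]
  -sum(p * log(p, base = log_base))
}

#' Mutual information between two expression profiles
#'
#' B-spline fractional-binning plug-in estimator: the joint bin distribution
#' is the sample average of outer products of the two weight rows, marginals
#' follow by summation, and MI is computed as `H(x) + H(y) - H(x, y)`
#' (algebraically identical to the sum over joint cells of
#' `p log p/(px py)`). Degenerate (constant) inputs give MI 0.
#'
#' @param x,y numeric vectors of equal length.
#' @param params a [clr_params()] object.
#' @return Mutual information (bits when `log_base = 2`).
#' @export
mutual_information <- function(x, y, params = clr_params()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  wx <- bspline_weights(x, params$n_bins, params$spline_order)
  wy <- bspline_weights(y, params$n_bins, params$spline_order)
  if (is.null(wx) || is.null(wy)) return(0)
  n <- length(x)
  joint <- crossprod(wx, wy) / n
  hx <- plugin_entropy(colSums(wx) / n, params$log_base)
  hy <- plugin_entropy(colSums(wy) / n, params$log_base)
  hxy <- plugin_entropy(as.vector(joint), params$log_base)
  hx + hy - hxy
}

#' All-pairs mutual-information matrix
#'
#' Computes every unordered gene pair once via one blockwise cross-product
#' of the stacked per-gene weight matrices, then mirrors; the diagonal holds
#' each gene's self-MI (its binned entropy). Constant genes get MI 0 to all
#' partners. Identical to looping [mutual_information()] over pairs, but
#' orders of magnitude faster.
#'
#' @param m an `ExpressionMatrix` (>= 3 genes; >= 4 samples recommended, a
#'   warning is raised below that).
#' @param params a [clr_params()] object.
#' @return A symmetric MI matrix with gene ids as dimnames.
#' @export
mi_matrix <- function(m, params = clr_params()) {
  v <- m$values
  G <- nrow(v)
  n <- ncol(v)
  if (G < 3L) stop("need at least 3 genes")
  if (n < 4L) warning("fewer than 4 samples; MI estimates will be unstable")
  nb <- params$n_bins
  W <- matrix(0, n, G * nb)
  degenerate <- logical(G)
  for (g in seq_len(G)) {
    w <- bspline_weights(v[g, ], nb, params$spline_order)
    if (is.null(w)) degenerate[g] <- TRUE
    else W[, (g - 1L) * nb + seq_len(nb)] <- w
  }
  C <- crossprod(W) / n                      # every pair's joint distribution
  L <- C * log(ifelse(C > 0, C, 1), base = params$log_base)
  A <- matrix(0, G * nb, G)
  A[cbind(seq_len(G * nb), rep(seq_len(G), each = nb))] <- 1
  h_joint <- -crossprod(A, L) %*% A
  marg <- colSums(W) / n
  h_marg <- vapply(seq_len(G), function(g)
    plugin_entropy(marg[(g - 1L) * nb + seq_len(nb)], params$log_base), 0)
  mi <- outer(h_marg, h_marg, "+") - h_joint
  mi[mi < 0] <- 0                            # guard tiny negative round-off
  if (any(degenerate)) {
    mi[degenerate, ] <- 0
    mi[, degenerate] <- 0
  }
  mi <- (mi + t(mi)) / 2                     # exact symmetry
  dimnames(mi) <- list(gene_ids(m), gene_ids(m))
  mi
}

#' CLR background-corrected scores
#'
#' For each gene, its MI values to all other genes (self excluded) form a
#' background distribution with mean and population (n-denominator) standard
#' deviation; the pair z-scores are `z = (MI - mean) / sd`, clamped at 0
#' when `z_clamp` is set, and combined into the composite
#' `sqrt(z_a^2 + z_b^2)`. Genes whose background sd is zero get z = 0.
#'
#' @param mi symmetric MI matrix from [mi_matrix()].
#' @param params a [clr_params()] object.
#' @return A list of class `clr_scores`: `scores` (symmetric composite
#'   matrix, zero diagonal), `z` (row-wise background z matrix, `z[i, j]` is
#'   gene i's z for the pair), `mi`, `params`.
#' @export
clr_scores <- function(mi, params = clr_params()) {
  G <- nrow(mi)
  if (G < 3L) stop("background undefined with fewer than 3 genes")
  M <- mi
  diag(M) <- NA
  mu <- rowMeans(M, na.rm = TRUE)
  sd_pop <- sqrt(rowMeans((M - mu)^2, na.rm = TRUE))
  z <- (M - mu) / ifelse(sd_pop > 0, sd_pop, Inf)
  z[is.na(z)] <- 0
  if (params$z_clamp) z[z < 0] <- 0
  scores <- sqrt(z^2 + t(z)^2)
  diag(scores) <- 0
  structure(list(scores = scores, z = z, mi = mi, params = params),
            class = "clr_scores")
}

#' Threshold CLR scores into a network
#'
#' Retains undirected edges with composite score >= `z_cutoff` (inclusive).
#'
#' @param scores a `clr_scores` object.
#' @param z_cutoff threshold; defaults to the cutoff stored in the scores'
#'   parameters.
#' @return A list of class `clr_network`: `edges` (data frame `gene_a`,
#'   `gene_b`, `clr_score`, `z_a`, `z_b`, `mi`, sorted by decreasing score),
#'   `nodes` (genes with >= 1 edge), `gene_ids` (full universe), `params`.
#' @export
threshold_network <- function(scores, z_cutoff = NULL) {
  if (!inherits(scores, "clr_scores")) stop("expected a 'clr_scores' object")
  if (is.null(z_cutoff)) z_cutoff <- scores$params$z_cutoff
  S <- scores$scores
  ids <- rownames(S)
  sel <- which(upper.tri(S) & S >= z_cutoff, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = ids[sel[, 1L]], gene_b = ids[sel[, 2L]],
    clr_score = S[sel],
    z_a = scores$z[sel],
    z_b = scores$z[sel[, c(2L, 1L), drop = FALSE]],
    mi = scores$mi[sel],
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$clr_score, edges$gene_a, edges$gene_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 gene_ids = ids,
                 params = utils::modifyList(scores$params,
                                            list(z_cutoff = z_cutoff))),
            class = "clr_network")
}

#' @export
print.clr_network <- function(x, ...) {
  cat(sprintf("clr_network: %d nodes, %d edges (cutoff %g, %d bins, order %d)\n",
              length(x$nodes), nrow(x$edges), x$params$z_cutoff,
              x$params$n_bins, x$params$spline_order))
  invisible(x)
}

#' Collapse probes to gene symbols by maximum variance
#'
#' When several probes map to one gene symbol, the probe with the largest
#' variance across samples represents the symbol, the usual rule before
#' network inference so each node is one gene.
#'
#' @param m an `ExpressionMatrix` whose rows are probes.
#' @param symbol_map named character vector: `names` are probe ids, values
#'   are gene symbols. Probes absent from the map are dropped.
#' @return An `ExpressionMatrix` with one row per symbol; an attribute
#'   `probe_of` records which probe was chosen for each symbol.
#' @export
collapse_probes <- function(m, symbol_map) {
  probes <- intersect(gene_ids(m), names(symbol_map))
  if (!length(probes)) stop("no probes of the matrix appear in the map")
  vars <- apply(m$values[probes, , drop = FALSE], 1L, stats::var)
  sym <- symbol_map[probes]
  chosen <- vapply(split(probes, sym),
                   function(p) p[which.max(vars[p])], "")
  out <- em_subset(m, genes = match(chosen, gene_ids(m)))
  rownames(out$values) <- names(chosen)
  if (!is.null(out$flags)) rownames(out$flags) <- names(chosen)
  attr(out, "probe_of") <- chosen
  out
}
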