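# Independent oracle implementations used to check the package's fast paths.
# These are deliberately naive (recursions, enumerations, brute force) and
# share no code with the implementations they verify.

# Cox-de Boor recursion for a single B-spline basis function B_{i,k} on a
# non-decreasing knot vector (1-based i, order k = degree + 1).
deboor_basis <- function(x, knots, i, k) {
  if (k == 1L) {
    # half-open bins, except the last interval which is closed at the top
    lo <- knots[i]; hi <- knots[i + 1L]
    if (lo == hi) return(0)
    last <- max(which(knots < max(knots)))  # index of last nonzero interval
    if (i == last) as.numeric(x >= lo & x <= hi)
    else as.numeric(x >= lo & x < hi)
  } else {
    d1 <- knots[i + k - 1L] - knots[i]
    d2 <- knots[i + k] - knots[i + 1L]
    t1 <- if (d1 > 0) (x - knots[i]) / d1 * deboor_basis(x, knots, i, k - 1L) else 0
    t2 <- if (d2 > 0) (knots[i + k] - x) / d2 * deboor_basis(x, knots, i + 1L, k - 1L) else 0
    t1 + t2
  }
}

deboor_weights <- function(x, n_bins, order) {
  rng <- range(x)
  top <- n_bins - order + 1L
  z <- (x - rng[1L]) / (rng[2L] - rng[1L]) * top
  knots <- c(rep(0, order), seq_len(top - 1L), rep(top, order))
  sapply(seq_len(n_bins), function(i)
    vapply(z, function(zz) deboor_basis(zz, knots, i, order), 0))
}

# plug-in MI with equal-width hard bins (max value goes in the last bin)
hard_binned_mi <- function(x, y, n_bins, log_base = 2) {
  bin_of <- function(v) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) return(rep(1L, length(v)))
    b <- floor((v - rng[1L]) / (rng[2L] - rng[1L]) * n_bins) + 1L
    pmin(b, n_bins)
  }
  bx <- bin_of(x); by <- bin_of(y)
  joint <- table(factor(bx, 1:n_bins), factor(by, 1:n_bins)) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (a in 1:n_bins) for (b in 1:n_bins)
    if (joint[a, b] > 0)
      s <- s + joint[a, b] * log(joint[a, b] / (px[a] * py[b]), base = log_base)
  s
}

hard_binned_entropy <- function(x, n_bins, log_base = 2) {
  rng <- range(x)
  b <- pmin(floor((x - rng[1L]) / (rng[2L] - rng[1L]) * n_bins) + 1L, n_bins)
  p <- as.vector(table(factor(b, 1:n_bins))) / length(x)
  p <- p[p > 0]
  -sum(p * log(p, base = log_base))
}

# brute-force UPGMA: keeps all cluster member lists and recomputes every
# inter-cluster average from the original dissimilarity matrix at each step
brute_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1L]) best <- c(avg, i, j)
    }
    heights <- c(heights, best[1L])
    clusters <- c(clusters[-c(best[2L], best[3L])],
                  list(c(clusters[[best[2L]]], clusters[[best[3L]]])))
  }
  heights
}

# cophenetic matrix by brute-force UPGMA (merge-height of the step joining
# each leaf pair), for topology+height comparison independent of leaf order
brute_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1L]) best <- c(avg, i, j)
    }
    a <- clusters[[best[2L]]]; b <- clusters[[best[3L]]]
    coph[a, b] <- best[1L]; coph[b, a] <- best[1L]
    clusters <- c(clusters[-c(best[2L], best[3L])], list(c(a, b)))
  }
  coph
}

# union-find connected components over an edge data frame
union_find_components <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges$gene_a[r]); rb <- find(edges$gene_b[r])
    if (ra != rb) parent[[ra]] <- rb
  }
  split(nodes, vapply(nodes, find, ""))
}

# random ExpressionMatrix fixture
random_em <- function(n_genes = 6, n_samples = 5,
                      scale = "intensity", seed = NULL, flags = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(stats::runif(n_genes * n_samples, 10, 1000),
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  f <- if (flags) matrix(TRUE, n_genes, n_samples) else NULL
  expression_matrix(v, scale = scale, flags = f)
}

# small two-group design frame
toy_design <- function(sample_ids, dose, time_h = 24, system = "in_vivo",
                       compound = "TNT") {
  data.frame(sample_id = sample_ids, system = system, compound = compound,
             dose = dose, time_h = time_h,
             replicate = stats::ave(dose, dose, FUN = seq_along),
             is_control = dose == 0, stringsAsFactors = FALSE)
}
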