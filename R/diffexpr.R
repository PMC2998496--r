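#' Classical one-way fixed-effects ANOVA
#'
#' Returns the F statistic and upper-tail p value for a difference in group
#' means. Degenerate input with zero within-group variance and equal means
#' returns `F = 0, p = 1` (no evidence of a difference) so that constant
#' genes flow through a genome-wide scan without erroring.
#'
#' @param groups list of numeric vectors, one per group, each of length >= 2.
#' @return A list with `statistic` (F) and `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  n <- lengths(groups)
  if (any(n < 2L)) stop("every group needs at least 2 values")
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L
  df2 <- N - k
  if (ss_within == 0) {
    if (ss_between == 0) return(list(statistic = 0, p_value = 1))
    return(list(statistic = Inf, p_value = 0))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Largest fold change between any pair of group means
#'
#' On linear scale this is `max(means) / min(means)`; log2 means are
#' exponentiated first. Always >= 1 by the max/min convention.
#'
#' @param group_means numeric vector of group means (length >= 2).
#' @param scale `"linear"` (means must be positive) or `"log2"`.
#' @return The maximum pairwise ratio.
#' @export
max_pairwise_fold_change <- function(group_means, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (length(group_means) < 2L) stop("need at least 2 group means")
  if (scale == "log2") group_means <- 2^group_means
  if (any(group_means <= 0)) stop("linear-scale group means must be positive")
  max(group_means) / min(group_means)
}

# internal: linear-scale group means of one gene's log2 values
linear_group_means <- function(x, groups, scale) {
  lin <- if (scale == "log2") 2^x else x
  vapply(split(lin, groups), mean, 0)
}

gene_list_result <- function(tab, test, alpha, fold, contrast) {
  structure(tab, class = c("GeneListResult", "data.frame"),
            test = test, alpha = alpha, fold_threshold = fold,
            p_rule = "p < alpha (strict)", fold_rule = "fc >= fold (inclusive)",
            contrast = contrast)
}

#' @export
print.GeneListResult <- function(x, ...) {
  cat(sprintf("GeneListResult: %s, alpha %g, fold >= %g (%s)\n",
              attr(x, "test"), attr(x, "alpha"), attr(x, "fold_threshold"),
              attr(x, "contrast")))
  cat(sprintf("  %d of %d genes pass\n", sum(x$passes), nrow(x)))
  invisible(x)
}

#' Dose-series ANOVA differential-expression filter
#'
#' Per gene, a one-way ANOVA across dose groups at one time point; a gene
#' passes when `p < alpha` and the largest fold change between any pair of
#' dose-group means is at least `fold`. Direction is the sign of the
#' top-dose mean relative to the control (zero-dose) mean, reported only for
#' passing genes. BH-adjusted q values are included for transparency but do
#' not enter the pass rule.
#'
#' @param m an `ExpressionMatrix` (log2 scale recommended; fold changes are
#'   computed on linear-scale group means).
#' @param design design table covering the samples of `m`.
#' @param time_h the time point to test.
#' @param alpha p-value cutoff (strict `<`).
#' @param fold fold-change threshold (inclusive `>=`); `NA` disables the
#'   fold filter.
#' @return A `GeneListResult` data frame: `gene_id`, `p_value`, `q_value`,
#'   `max_fc`, `direction`, `passes`.
#' @export
anova_dose_filter <- function(m, design, time_h, alpha = 0.05, fold = 1.5) {
  design <- match_design(m, design)
  sel <- design$time_h == time_h
  if (!any(sel)) stop("time point ", time_h, " not present in design")
  sub <- em_subset(m, samples = which(sel))
  d <- design[sel, , drop = FALSE]
  doses <- sort(unique(d$dose))
  if (length(doses) < 2L) stop("need at least 2 dose groups")
  grp <- factor(d$dose, levels = doses)
  if (any(table(grp) < 2L)) stop("every dose group needs >= 2 samples")
  idx <- split(seq_along(grp), grp)
  res <- apply_de_scan(sub, idx, alpha, fold,
                       direction_pair = c(1L, length(doses)))
  gene_list_result(res, "one-way ANOVA across doses", alpha, fold,
                   sprintf("top dose vs control at %g h", time_h))
}

#' Two-group t-test differential-expression filter
#'
#' Unpaired Student (equal-variance) t-test of treated versus control
#' samples; Welch's correction is available behind `var_equal = FALSE`.
#' A gene passes when `p < alpha` and the treated/control fold change is at
#' least `fold`; direction is up when the treated mean exceeds the control
#' mean.
#'
#' @inheritParams anova_dose_filter
#' @param var_equal use the pooled-variance Student t-test (default) or
#'   Welch's unequal-variance form.
#' @return A `GeneListResult` data frame.
#' @export
ttest_filter <- function(m, design, alpha = 0.05, fold = 1.5,
                         var_equal = TRUE) {
  design <- match_design(m, design)
  ctrl <- which(design$is_control)
  trt <- which(!design$is_control)
  if (length(ctrl) < 2L || length(trt) < 2L)
    stop("need >= 2 control and >= 2 treated samples")
  idx <- list(control = ctrl, treated = trt)
  res <- apply_de_scan(m, idx, alpha, fold, direction_pair = c(1L, 2L),
                       test = if (var_equal) "student" else "welch")
  gene_list_result(res, if (var_equal) "unpaired Student t-test"
                        else "Welch t-test",
                   alpha, fold, "treated vs control")
}

# internal: scan all genes with either ANOVA (k groups) or a t-test (2
# groups); direction_pair gives the (reference, contrast) group indices.
apply_de_scan <- function(m, idx, alpha, fold, direction_pair,
                          test = c("anova", "student", "welch")) {
  test <- match.arg(test)
  v <- m$values
  G <- nrow(v)
  p <- numeric(G)
  fc <- numeric(G)
  dir_sign <- numeric(G)
  two_group <- length(idx) == 2L && test != "anova"
  for (g in seq_len(G)) {
    groups <- lapply(idx, function(i) v[g, i])
    if (two_group) {
      tt <- stats::t.test(groups[[2L]], groups[[1L]],
                          var.equal = (test == "student"))
      p[g] <- tt$p.value
    } else {
      p[g] <- one_way_anova(groups)$p_value
    }
    gm <- linear_group_means(v[g, unlist(idx)],
                             rep(seq_along(idx), lengths(idx)), m$scale)
    fc[g] <- max(gm) / min(gm)
    dir_sign[g] <- sign(gm[direction_pair[2L]] - gm[direction_pair[1L]])
  }
  passes <- (p < alpha) & (if (is.na(fold)) TRUE else fc >= fold)
  direction <- ifelse(!passes, "none", ifelse(dir_sign >= 0, "up", "down"))
  data.frame(gene_id = gene_ids(m), p_value = p,
             q_value = stats::p.adjust(p, "BH"),
             max_fc = fc, direction = direction, passes = passes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Union of per-time-point differential-expression calls
#'
#' Runs [anova_dose_filter()] at each time point present in the design and
#' returns the union of passing gene sets, mirroring an "all doses and time
#' points" gene universe.
#'
#' @inheritParams anova_dose_filter
#' @param time_points time points to scan (default: all in the design).
#' @return A list: `genes` (union of passing gene ids), `per_time` (named
#'   list of `GeneListResult`s).
#' @export
anova_dose_filter_union <- function(m, design, time_points = NULL,
                                    alpha = 0.05, fold = 1.5) {
  design <- match_design(m, design)
  if (is.null(time_points)) time_points <- sort(unique(design$time_h))
  per_time <- lapply(time_points, function(t)
    anova_dose_filter(m, design, t, alpha = alpha, fold = fold))
  names(per_time) <- paste0("t", time_points)
  genes <- unique(unlist(lapply(per_time, function(r) r$gene_id[r$passes])))
  list(genes = genes, per_time = per_time)
}

#' Venn partition of two gene sets
#'
#' @param a,b character vectors of gene identifiers.
#' @return A list with `a_only`, `common`, `b_only` (sorted id vectors) and
#'   `counts` (named integer vector).
#' @export
intersect_gene_lists <- function(a, b) {
  a <- unique(a); b <- unique(b)
  common <- sort(intersect(a, b))
  a_only <- sort(setdiff(a, b))
  b_only <- sort(setdiff(b, a))
  list(a_only = a_only, common = common, b_only = b_only,
       counts = c(a_only = length(a_only), common = length(common),
                  b_only = length(b_only)))
}

#' Overlap percentage, rounded to the nearest integer
#'
#' `round(100 * common / reference)` with halves rounded away from zero, the
#' convention used when reporting "N transcripts (X% of ...)".
#'
#' @param common overlap count.
#' @param reference reference set size (> 0).
#' @return Integer percentage.
#' @export
venn_percentage <- function(common, reference) {
  if (reference <= 0) stop("reference count must be positive")
  if (common > reference) stop("common cannot exceed reference")
  as.integer(floor(100 * common / reference + 0.5))
}

#' Cross-platform concordance correlation
#'
#' Pearson product-moment correlation between two vectors of paired log2
#' ratios (e.g. microarray vs QPCR measurements of the same genes and
#' conditions).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Pearson r in `[-1, 1]`.
#' @export
concordance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input; correlation undefined")
  stats::cor(x, y)
}
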