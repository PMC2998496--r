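test_that("one-way ANOVA matches the classical F test", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(g) rnorm(sample(3:6, 1), mean = g / 2))
    ours <- one_way_anova(groups)
    x <- unlist(groups)
    g <- factor(rep(seq_len(k), lengths(groups)))
    ref <- oneway.test(x ~ g, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate cases follow the no-evidence convention", {
  same_mean <- list(c(1, 2, 3), c(3, 2, 1))
  res <- one_way_anova(same_mean)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res0 <- one_way_anova(list(c(5, 5), c(5, 5, 5)))
  expect_equal(res0$p_value, 1)
  expect_equal(one_way_anova(list(c(1, 1), c(2, 2)))$p_value, 0)
  expect_error(one_way_anova(list(1, c(2, 3))), "at least 2 values")
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
})

test_that("for two groups F equals the squared Student t", {
  set.seed(22)
  for (i in 1:50) {
    a <- rnorm(4); b <- rnorm(5, 0.5)
    f <- one_way_anova(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("max pairwise fold change uses the max/min convention", {
  expect_equal(max_pairwise_fold_change(c(10, 15)), 1.5)
  expect_equal(max_pairwise_fold_change(c(7, 7, 7)), 1)
  expect_equal(max_pairwise_fold_change(c(4, 6, 10)), 2.5)
  expect_equal(max_pairwise_fold_change(log2(c(4, 6, 10)), scale = "log2"), 2.5)
  expect_gte(max_pairwise_fold_change(c(2, 3, 2.4)), 1)
  expect_error(max_pairwise_fold_change(c(-1, 2)), "positive")
  expect_error(max_pairwise_fold_change(5), "2 group")
})

make_dose_fixture <- function(n_null = 8, seed = 23) {
  set.seed(seed)
  doses <- rep(c(0, 4.8, 48, 96, 192), each = 3)
  ids <- sprintf("s%02d", seq_along(doses))
  v <- matrix(rnorm(n_null * length(doses), 10, 0.1), n_null, length(doses))
  planted <- 10 + c(rep(0, 12), rep(1, 3)) + rnorm(length(doses), 0, 0.01)
  flat <- rep(10, length(doses))
  v <- rbind(v, planted, flat)
  dimnames(v) <- list(c(sprintf("null%02d", 1:n_null), "planted", "flat"), ids)
  list(m = expression_matrix(v, "log2"),
       design = toy_design(ids, doses))
}

test_that("the dose-series ANOVA filter finds planted shifts and skips constants", {
  fx <- make_dose_fixture()
  res <- anova_dose_filter(fx$m, fx$design, time_h = 24)
  expect_s3_class(res, "GeneListResult")
  expect_true(res$passes[res$gene_id == "planted"])
  expect_identical(res$direction[res$gene_id == "planted"], "up")
  expect_false(res$passes[res$gene_id == "flat"])
  expect_equal(res$max_fc[res$gene_id == "flat"], 1)
  expect_identical(res$direction[res$gene_id == "flat"], "none")
  # pass implies both sub-criteria
  expect_true(all(res$p_value[res$passes] < 0.05))
  expect_true(all(res$max_fc[res$passes] >= 1.5))
  expect_true(all(res$max_fc >= 1))
  expect_error(anova_dose_filter(fx$m, fx$design, time_h = 48), "time point")
})

test_that("the t-test filter calls direction and matches a hand-computed t", {
  ids <- sprintf("s%d", 1:6)
  design <- data.frame(sample_id = ids, system = "in_vitro", compound = "TNT",
                       dose = rep(c(0, 10), each = 3), time_h = 24,
                       replicate = rep(1:3, 2),
                       is_control = rep(c(TRUE, FALSE), each = 3))
  ctl <- c(2.1, 1.9, 2.0); trt <- c(3.2, 3.0, 3.1)
  v <- rbind(up_gene = c(ctl, trt), flat = rep(c(5, 5.001), 3))
  colnames(v) <- ids
  m <- expression_matrix(v, "log2")
  res <- ttest_filter(m, design)
  # oracle: pooled-variance t on the toy numbers
  sp <- sqrt((var(ctl) * 2 + var(trt) * 2) / 4)
  tstat <- (mean(trt) - mean(ctl)) / (sp * sqrt(1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(abs(tstat), df = 4, lower.tail = FALSE)
  expect_equal(res$p_value[res$gene_id == "up_gene"], p_oracle,
               tolerance = 1e-12)
  expect_true(res$passes[res$gene_id == "up_gene"])
  expect_identical(res$direction[res$gene_id == "up_gene"], "up")
  expect_false(res$passes[res$gene_id == "flat"])
  # treated = 2x control exactly, tiny noise -> passes, up
  set.seed(24)
  v2 <- rbind(dbl = log2(c(100, 101, 99, 200, 202, 198)))
  colnames(v2) <- ids
  res2 <- ttest_filter(expression_matrix(v2, "log2"), design)
  expect_true(res2$passes)
  expect_identical(res2$direction, "up")
  expect_error(ttest_filter(m, design[-1, ]), "no row")
})

test_that("filters are invariant to gene and sample order", {
  fx <- make_dose_fixture(seed = 25)
  res <- anova_dose_filter(fx$m, fx$design, 24)
  gperm <- sample(nrow(fx$m$values))
  sperm <- sample(ncol(fx$m$values))
  mp <- expression_matrix(fx$m$values[gperm, sperm], scale = "log2")
  resp <- anova_dose_filter(mp, fx$design, 24)
  resp <- resp[match(res$gene_id, resp$gene_id), ]
  expect_equal(res$p_value, resp$p_value, tolerance = 1e-12)
  expect_identical(res$passes, resp$passes)
})

test_that("adding the fold filter can only shrink the pass set", {
  set.seed(26)
  doses <- rep(c(0, 4.8, 48, 96, 192), each = 3)
  ids <- sprintf("s%02d", seq_along(doses))
  v <- matrix(rnorm(200 * length(doses), 8, 0.5), 200, length(doses),
              dimnames = list(sprintf("g%03d", 1:200), ids))
  m <- expression_matrix(v, "log2")
  design <- toy_design(ids, doses)
  with_fold <- anova_dose_filter(m, design, 24, fold = 1.5)
  no_fold <- anova_dose_filter(m, design, 24, fold = NA)
  expect_lte(sum(with_fold$passes), sum(no_fold$passes))
  expect_true(all(with_fold$gene_id[with_fold$passes] %in%
                  no_fold$gene_id[no_fold$passes]))
})

test_that("Venn partitions are disjoint and exhaustive", {
  r <- intersect_gene_lists(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(unname(r$counts), c(1, 2, 1))
  expect_identical(r$common, c("B", "C"))
  same <- intersect_gene_lists(letters[1:4], letters[1:4])
  expect_equal(unname(same$counts), c(0, 4, 0))
  set.seed(27)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    r <- intersect_gene_lists(a, b)
    blocks <- c(r$a_only, r$common, r$b_only)
    expect_identical(anyDuplicated(blocks), 0L)
    expect_setequal(blocks, union(a, b))
    # brute-force membership scan
    expect_setequal(r$common, unique(a[a %in% b]))
  }
})

test_that("overlap percentages round half away from zero", {
  expect_identical(venn_percentage(164, 214), 77L)
  expect_identical(venn_percentage(90, 127), 71L)
  expect_identical(venn_percentage(0, 10), 0L)
  expect_identical(venn_percentage(1, 8), 13L)   # 12.5 rounds up
  expect_error(venn_percentage(1, 0), "positive")
  expect_error(venn_percentage(5, 4), "exceed")
})

test_that("concordance correlation matches the covariance formula", {
  x <- c(1, 2, 3, 5)
  expect_equal(concordance_correlation(x, x), 1)
  expect_equal(concordance_correlation(x, -x), -1)
  y <- c(0.5, 1.9, 3.2, 4.1)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(concordance_correlation(x, y), r_oracle, tolerance = 1e-12)
  expect_error(concordance_correlation(c(1, 1, 1), y[1:3]), "variance")
  expect_error(concordance_correlation(1:2, 1:2), "3 paired")
})
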