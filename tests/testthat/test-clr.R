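test_that("B-spline weights form a partition of unity at every order", {
  set.seed(41)
  for (ord in 1:4) {
    x <- rnorm(200)
    w <- bspline_weights(x, n_bins = 10, spline_order = ord)
    expect_true(all(w >= -1e-12))
    expect_equal(rowSums(w), rep(1, 200), tolerance = 1e-12)
  }
  expect_null(bspline_weights(rep(3, 5)))
  expect_error(bspline_weights(c(1, NA, 2)), "finite")
  expect_error(bspline_weights(1:5, n_bins = 2, spline_order = 3), "n_bins")
})

test_that("order-1 weights reproduce equal-width hard binning", {
  set.seed(42)
  x <- runif(100, -3, 7)
  w <- bspline_weights(x, n_bins = 8, spline_order = 1)
  expect_true(all(w %in% c(0, 1)))
  bins_w <- apply(w, 1, which.max)
  bins_hard <- pmin(floor((x - min(x)) / (max(x) - min(x)) * 8) + 1, 8)
  expect_equal(bins_w, bins_hard, ignore_attr = TRUE)
  expect_equal(bins_w[which.max(x)], 8, ignore_attr = TRUE)
})

test_that("order-3 weights match the de Boor recursion oracle", {
  set.seed(43)
  x <- c(runif(50, 0, 1), 0.1234, 0)  # include the domain boundary
  x <- c(x, max(x))
  w <- bspline_weights(x, n_bins = 10, spline_order = 3)
  oracle <- deboor_weights(x, n_bins = 10, order = 3)
  expect_equal(w, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mutual information is symmetric, nonnegative and zero for constants", {
  set.seed(44)
  x <- rnorm(60); y <- rnorm(60)
  expect_equal(mutual_information(x, y), mutual_information(y, x),
               tolerance = 1e-12)
  expect_gte(mutual_information(x, y), 0)
  expect_equal(mutual_information(x, rep(1, 60)), 0)
  expect_error(mutual_information(x, y[-1]), "equal length")
})

test_that("order-1 self-MI equals the hard-binned entropy", {
  set.seed(45)
  x <- runif(500)
  p <- clr_params(n_bins = 10, spline_order = 1)
  expect_equal(mutual_information(x, x, p), hard_binned_entropy(x, 10),
               tolerance = 1e-12)
})

test_that("MI is invariant under positive affine rescaling", {
  set.seed(46)
  x <- rnorm(80); y <- x + rnorm(80, 0, 0.5)
  base <- mutual_information(x, y)
  expect_equal(mutual_information(3.7 * x + 11, y), base, tolerance = 1e-10)
  expect_equal(mutual_information(x, 0.01 * y - 5), base, tolerance = 1e-10)
})

test_that("the MI matrix equals looped pairwise calls and handles copies", {
  set.seed(47)
  v <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("g", 1:5), sprintf("s%02d", 1:30)))
  v[2, ] <- v[1, ]  # duplicated gene rows
  m <- expression_matrix(v, "log2")
  p <- clr_params()
  mi <- mi_matrix(m, p)
  for (i in 1:5) for (j in i:5)
    expect_equal(mi[i, j], mutual_information(v[i, ], v[j, ], p),
                 tolerance = 1e-12)
  expect_equal(mi[1, 2], mi[1, 1], tolerance = 1e-12)
  expect_equal(mi, t(mi))
  # sample permutation invariance
  perm <- sample(30)
  mi_p <- mi_matrix(expression_matrix(v[, perm], "log2"), p)
  expect_equal(mi, mi_p, tolerance = 1e-12)
  # degenerate gene row gets MI 0 everywhere
  v[3, ] <- 2.5
  mi_d <- mi_matrix(expression_matrix(v, "log2"), p)
  expect_true(all(mi_d[3, ] == 0))
})

test_that("independent variables have near-zero MI at large n", {
  set.seed(48)
  x <- runif(10000); y <- runif(10000)
  expect_lt(mutual_information(x, y), 0.05)
})

test_that("CLR scores standardize against per-gene backgrounds", {
  # flat off-diagonal MI -> all z = 0 -> all scores 0
  mi <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(mi) <- 2
  sc <- clr_scores(mi)
  expect_true(all(sc$scores == 0))
  # single elevated pair: score matches hand-computed row statistics
  set.seed(49)
  G <- 12
  mi2 <- matrix(abs(rnorm(G * G, 0.2, 0.02)), G)
  mi2 <- (mi2 + t(mi2)) / 2
  dimnames(mi2) <- list(sprintf("g%02d", 1:G), sprintf("g%02d", 1:G))
  mi2[1, 2] <- mi2[2, 1] <- 1.5
  sc2 <- clr_scores(mi2)
  z_hand <- function(i, j) {
    bg <- mi2[i, -i]
    max(0, (mi2[i, j] - mean(bg)) / sqrt(mean((bg - mean(bg))^2)))
  }
  expect_equal(sc2$scores[1, 2], sqrt(z_hand(1, 2)^2 + z_hand(2, 1)^2),
               tolerance = 1e-12)
  expect_equal(sc2$scores, t(sc2$scores), tolerance = 1e-12)
  expect_error(clr_scores(mi[1:2, 1:2]), "3 genes")
})

test_that("thresholding is inclusive and reports nodes with edges", {
  S <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  S["a", "b"] <- S["b", "a"] <- 2.5
  S["a", "c"] <- S["c", "a"] <- 1.9
  S["b", "c"] <- S["c", "b"] <- 2.0
  fake <- structure(list(scores = S, z = S / 2, mi = S / 10,
                         params = clr_params()), class = "clr_scores")
  net <- threshold_network(fake)
  expect_equal(nrow(net$edges), 2)          # 2.5 and the boundary 2.0
  expect_setequal(net$nodes, c("a", "b", "c"))
  empty <- threshold_network(fake, z_cutoff = 10)
  expect_equal(nrow(empty$edges), 0)
  allpairs <- threshold_network(fake, z_cutoff = 0)
  expect_equal(nrow(allpairs$edges), 3)
})

test_that("with order 1 the whole CLR pipeline equals a hard-binned one", {
  set.seed(50)
  v <- matrix(rnorm(15 * 20), 15, 20,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:20)))
  m <- expression_matrix(v, "log2")
  p <- clr_params(n_bins = 10, spline_order = 1)
  mi <- mi_matrix(m, p)
  oracle <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15)
    oracle[i, j] <- hard_binned_mi(v[i, ], v[j, ], 10)
  expect_equal(unname(mi), oracle, tolerance = 1e-12)
})

test_that("probe collapse keeps the highest-variance probe per symbol", {
  v <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1, 5, 9, 13), p3 = c(2, 2, 2, 2.1))
  colnames(v) <- paste0("s", 1:4)
  m <- expression_matrix(v, "log2")
  map <- c(p1 = "GENE1", p2 = "GENE1", p3 = "GENE2")
  cm <- collapse_probes(m, map)
  expect_setequal(gene_ids(cm), c("GENE1", "GENE2"))
  expect_equal(unname(cm$values["GENE1", ]), unname(v["p2", ]))
})

test_that("shuffling samples per gene destroys planted-edge recovery", {
  cfg <- sim_config(n_genes = 80, n_tfs = 6, targets_per_tf = 5,
                    shared_module_count = 3, n_compendium_conditions = 100,
                    seed = 5)
  tr <- generate_truth_networks(cfg)
  sim <- simulate_expression(tr$a, cfg, "compendium", stream = 1,
                             log2_output = TRUE)
  p <- clr_params()
  sc <- clr_scores(mi_matrix(sim$matrix, p), p)
  rec <- score_network_recovery(sc, tr$a)
  set.seed(51)
  vperm <- t(apply(sim$matrix$values, 1, sample))
  colnames(vperm) <- sample_ids(sim$matrix)
  sc_p <- clr_scores(mi_matrix(expression_matrix(vperm, "log2"), p), p)
  rec_p <- score_network_recovery(sc_p, tr$a)
  # planted edges are recovered on real data, and at chance level after
  # independent per-gene sample permutation; the z-standardization keeps the
  # background edge *rate* roughly constant, so recovery (not raw edge
  # count) is the quantity permutation destroys
  expect_gte(rec$recall, 0.9)
  expect_lt(rec_p$recall, 0.05 * rec$recall + 0.15)
  expect_lt(rec_p$aupr, 3 * rec_p$baseline)
  expect_gt(rec$aupr, 10 * rec$baseline)
})
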