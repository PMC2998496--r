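edge_df <- function(...) {
  pairs <- list(...)
  data.frame(gene_a = vapply(pairs, `[[`, "", 1),
             gene_b = vapply(pairs, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

test_that("network intersection keeps exactly the common unordered pairs", {
  a <- edge_df(c("n1", "n2"), c("n2", "n3"), c("n3", "n4"))
  b <- edge_df(c("n3", "n2"), c("n4", "n3"), c("n4", "n5"))
  cons <- intersect_networks(a, b)
  expect_equal(nrow(cons$edges), 2)
  expect_setequal(paste(cons$edges$gene_a, cons$edges$gene_b),
                  c("n2 n3", "n3 n4"))
  expect_length(cons$components, 1)
  expect_identical(cons$components[[1]]$nodes, c("n2", "n3", "n4"))
  # identical networks intersect to themselves
  self <- intersect_networks(a, a)
  expect_equal(nrow(self$edges), 3)
  # disjoint networks intersect to nothing
  none <- intersect_networks(a, edge_df(c("x", "y")))
  expect_equal(nrow(none$edges), 0)
  expect_length(none$components, 0)
})

test_that("intersection is commutative and bounded by the smaller network", {
  set.seed(61)
  nodes <- sprintf("n%02d", 1:12)
  rand_net <- function() {
    k <- sample(5:15, 1)
    e <- t(replicate(k, sort(sample(nodes, 2))))
    unique(data.frame(gene_a = e[, 1], gene_b = e[, 2],
                      stringsAsFactors = FALSE))
  }
  for (i in 1:10) {
    a <- rand_net(); b <- rand_net()
    ab <- intersect_networks(a, b)$edges
    ba <- intersect_networks(b, a)$edges
    expect_identical(ab[, c("gene_a", "gene_b")], ba[, c("gene_a", "gene_b")])
    expect_lte(nrow(ab), min(nrow(a), nrow(b)))
  }
})

test_that("components match a union-find oracle and are deterministically ordered", {
  e <- edge_df(c("a", "b"), c("b", "c"), c("d", "e"))
  comps <- connected_components(e)
  expect_length(comps, 2)
  expect_identical(comps[[1]]$nodes, c("a", "b", "c"))
  expect_identical(comps[[2]]$nodes, c("d", "e"))
  expect_identical(connected_components(e[0, ]), list())
  set.seed(62)
  for (i in 1:10) {
    nodes <- sprintf("n%02d", 1:15)
    k <- sample(4:18, 1)
    pairs <- t(replicate(k, sample(nodes, 2)))
    e <- unique(data.frame(gene_a = pmin(pairs[, 1], pairs[, 2]),
                           gene_b = pmax(pairs[, 1], pairs[, 2]),
                           stringsAsFactors = FALSE))
    got <- connected_components(e)
    oracle <- union_find_components(e)
    expect_setequal(lapply(got, function(cp) cp$nodes),
                    lapply(unname(oracle), sort))
  }
})

test_that("every component has >= 2 nodes and they partition the conserved node set", {
  set.seed(63)
  a <- edge_df(c("a", "b"), c("b", "c"), c("p", "q"), c("x", "y"))
  cons <- intersect_networks(a, a)
  all_nodes <- unlist(lapply(cons$components, `[[`, "nodes"))
  expect_identical(anyDuplicated(all_nodes), 0L)
  expect_setequal(all_nodes, unique(c(cons$edges$gene_a, cons$edges$gene_b)))
  expect_true(all(lengths(lapply(cons$components, `[[`, "nodes")) >= 2))
})

test_that("TF degree table counts incident edges with a strict hub threshold", {
  hub_edges <- data.frame(gene_a = rep("TF1", 16),
                          gene_b = sprintf("t%02d", 1:16))
  mid_edges <- data.frame(gene_a = rep("TF2", 15),
                          gene_b = sprintf("u%02d", 1:15))
  tab <- tf_degree_table(rbind(hub_edges, mid_edges),
                         tf_ids = c("TF1", "TF2", "TF3"))
  expect_equal(tab$degree[tab$tf == "TF1"], 16)
  expect_true(tab$highlight[tab$tf == "TF1"])     # over 15 connections
  expect_false(tab$highlight[tab$tf == "TF2"])    # exactly 15 is not "over"
  expect_equal(tab$degree[tab$tf == "TF3"], 0)    # absent TF reported at 0
})

test_that("degree-ratio flags follow the 2x convention with zero handling", {
  fl <- degree_ratio_flags(c(TF1 = 10, TF2 = 6, TF3 = 3, TF4 = 0),
                           c(TF1 = 4, TF2 = 4, TF3 = 0, TF4 = 0))
  expect_true(fl$flagged[fl$tf == "TF1"])    # 10 >= 2 x 4
  expect_false(fl$flagged[fl$tf == "TF2"])   # 6 < 2 x 4
  expect_true(fl$flagged[fl$tf == "TF3"])    # positive vs zero
  expect_false(fl$flagged[fl$tf == "TF4"])   # zero vs zero
  expect_identical(fl$higher_in[fl$tf == "TF1"], "a")
})

test_that("direction agreement tracks cross-system concordance per component", {
  a <- edge_df(c("g1", "g2"), c("g2", "g3"), c("h1", "h2"), c("k1", "k2"))
  dirs_a <- c(g1 = "down", g2 = "down", g3 = "down",
              h1 = "up", h2 = "down",            # concordant but mixed signs
              k1 = "up", k2 = "up")
  dirs_b <- c(g1 = "down", g2 = "down", g3 = "down",
              h1 = "up", h2 = "down",
              k1 = "up", k2 = "down")            # k2 flips between systems
  cons <- intersect_networks(a, a, directions_a = dirs_a, directions_b = dirs_b)
  byfirst <- stats::setNames(cons$components,
                             vapply(cons$components, function(cp) cp$nodes[1], ""))
  expect_true(byfirst$g1$direction_agreement)
  expect_identical(byfirst$g1$module_direction, "down")   # coherently repressed
  expect_true(byfirst$h1$direction_agreement)
  expect_identical(byfirst$h1$module_direction, "mixed")
  expect_false(byfirst$k1$direction_agreement)            # discordant member
})

test_that("recovery scoring restricts candidates to regulator-incident pairs", {
  truth <- data.frame(regulator = c("TF1", "TF1"), target = c("g1", "g2"))
  S <- matrix(0, 4, 4,
              dimnames = list(c("TF1", "g1", "g2", "g3"),
                              c("TF1", "g1", "g2", "g3")))
  S["TF1", "g1"] <- S["g1", "TF1"] <- 5
  S["TF1", "g2"] <- S["g2", "TF1"] <- 4
  S["g1", "g2"] <- S["g2", "g1"] <- 6   # co-target pair: excluded from scoring
  fake <- structure(list(scores = S, z = S, mi = S, params = clr_params()),
                    class = "clr_scores")
  r <- score_network_recovery(fake, truth)
  expect_equal(r$n_candidates, 3)       # TF1-g1, TF1-g2, TF1-g3
  expect_equal(r$aupr, 1)
  expect_equal(r$precision_at_k, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)
})

test_that("edge lists round-trip through TSV, SIF and GraphML", {
  e <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                  clr_score = c(3.2, 2.1), z_a = c(2, 1), z_b = c(2.5, 1.8),
                  mi = c(0.9, 0.4), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(e, f)
  expect_equal(read_edge_list(f), e)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(e, sif)
  expect_identical(readLines(sif), c("a\tclr\tb", "b\tclr\tc"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(e, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
})
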