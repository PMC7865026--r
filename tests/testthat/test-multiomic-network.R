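rand_block <- function(n, p, seed, prefix = "f") {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(paste0("s", seq_len(n)),
                         paste0(prefix, seq_len(p))))
}

test_that("sPLS score identities: self-association and univariate Pearson", {
  a <- rand_block(12, 5, 1, "x")
  el <- pairwise_spls_associations(a, a, n_components = 2,
                                   keep_fraction = 1, n_perm = 0)
  expect_equal(el$weight[el$u == el$v], rep(1, 5), tolerance = 1e-10)

  x <- rand_block(10, 1, 2, "x")
  y <- rand_block(10, 1, 3, "y")
  el <- pairwise_spls_associations(x, y, n_components = 1,
                                   keep_fraction = 1, n_perm = 0)
  expect_equal(el$weight, drop(cor(x, y)), tolerance = 1e-8)

  # symmetry and sign of the raw correlation on a correlated toy
  set.seed(4)
  base <- rnorm(12)
  xa <- cbind(p1 = base + rnorm(12, 0, 0.2), p2 = -base + rnorm(12, 0, 0.2))
  rownames(xa) <- paste0("s", 1:12)
  xb <- cbind(q1 = base + rnorm(12, 0, 0.2))
  rownames(xb) <- paste0("s", 1:12)
  ab <- pairwise_spls_associations(xa, xb, 1, 1, n_perm = 0)
  ba <- pairwise_spls_associations(xb, xa, 1, 1, n_perm = 0)
  expect_equal(ab$weight[ab$u == "p1"], ba$weight[ba$v == "p1"],
               tolerance = 1e-10)
  expect_gt(ab$weight[ab$u == "p1"], 0)
  expect_lt(ab$weight[ab$u == "p2"], 0)
  expect_equal(sign(ab$weight),
               unname(sign(drop(cor(xa, xb)))))

  expect_error(pairwise_spls_associations(xa[1:3, ], xb), ">= 4")
})

test_that("permutation p-values are seeded and reproducible bit-for-bit", {
  a <- rand_block(10, 8, 5, "a")
  b <- rand_block(10, 8, 6, "b")
  e1 <- pairwise_spls_associations(a, b, 2, 0.5, n_perm = 50, seed = 99)
  e2 <- pairwise_spls_associations(a, b, 2, 0.5, n_perm = 50, seed = 99)
  expect_identical(e1, e2)
  e3 <- pairwise_spls_associations(a, b, 2, 0.5, n_perm = 50, seed = 100)
  expect_false(identical(e1$p, e3$p))
})

test_that("merge_networks filters, deduplicates, and matches a hand-drawn union", {
  kinds <- c(g1 = "gene", g2 = "gene", m1 = "mirna", c1 = "cytokine")
  l1 <- data.frame(u = c("g1", "g2"), v = c("m1", "m1"),
                   weight = c(0.8, 0.3), p = c(0.01, 0.01))
  l2 <- data.frame(u = c("m1", "c1"), v = c("g1", "g1"),
                   weight = c(-0.9, 0.5), p = c(0.02, 0.2))
  l3 <- data.frame(u = "c1", v = "g2", weight = 0.45, p = 0.03)
  net <- merge_networks(list(l1, l2, l3), kinds, score_min = 0.4,
                        p_max = 0.05)
  # hand union: g1-m1 keeps the larger |weight| (-0.9); g2-m1 fails
  # score_min; c1-g1 fails p; c1-g2 survives
  expect_setequal(paste(net$edges$u, net$edges$v),
                  c("g1 m1", "c1 g2"))
  expect_equal(net$edges$weight[net$edges$u == "g1"], -0.9)
  expect_setequal(net$nodes$id, c("g1", "m1", "c1", "g2"))
  expect_equal(net$nodes$kind[net$nodes$id == "c1"], "cytokine")

  # raising score_min shrinks the edge set monotonically
  for (smin in c(0.2, 0.5, 0.85)) {
    sub <- merge_networks(list(l1, l2, l3), kinds, score_min = smin,
                          p_max = NULL)
    hi <- merge_networks(list(l1, l2, l3), kinds, score_min = smin + 0.1,
                         p_max = NULL)
    expect_true(all(paste(hi$edges$u, hi$edges$v) %in%
                    paste(sub$edges$u, sub$edges$v)))
  }
})

test_that("detect_communities separates disconnected triangles; singleton ok", {
  kinds <- stats::setNames(rep("gene", 6), paste0("g", 1:6))
  tri <- function(a, b, c) data.frame(u = c(a, b, a), v = c(b, c, c),
                                      weight = 0.9, p = NA_real_)
  net <- merge_networks(list(tri("g1", "g2", "g3"), tri("g4", "g5", "g6")),
                        kinds, score_min = 0.4, p_max = NULL)
  net <- detect_communities(net, seed = 3)
  expect_equal(length(unique(net$communities)), 2)
  expect_equal(length(unique(net$communities[c("g1", "g2", "g3")])), 1)

  single <- merge_networks(list(data.frame(u = "g1", v = "g2",
                                           weight = 0.9, p = NA_real_)),
                           kinds, score_min = 0.4, p_max = NULL)
  expect_equal(length(unique(detect_communities(single)$communities)), 1)
})

test_that("community detection recovers a planted two-block partition", {
  hits <- vapply(seed_stream(31, 20), function(s) {
    set.seed(s)
    n <- 40
    ids <- sprintf("n%02d", 1:n)
    block <- rep(1:2, each = 20)
    edges <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p_edge <- if (block[i] == block[j]) 0.9 else 0.05
      if (runif(1) < p_edge)
        edges <- rbind(edges, data.frame(u = ids[i], v = ids[j],
                                         weight = 0.8, p = NA_real_))
    }
    net <- merge_networks(list(edges),
                          stats::setNames(rep("gene", n), ids),
                          score_min = 0.4, p_max = NULL)
    net <- detect_communities(net, seed = s)
    com <- net$communities[ids]
    tab <- table(com, block)
    sum(apply(tab, 2, max)) / n
  }, numeric(1))
  expect_gte(mean(hits >= 0.95), 0.95)
})

test_that("eigenvector centrality matches the power-iteration oracle", {
  for (s in seed_stream(17, 10)) {
    set.seed(s)
    n <- sample(8:50, 1)
    ids <- sprintf("n%02d", seq_len(n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- pairs[runif(nrow(pairs)) < 0.12, , drop = FALSE]
    if (!nrow(sel)) next
    edges <- data.frame(u = ids[sel[, 1]], v = ids[sel[, 2]],
                        weight = runif(nrow(sel), -1, 1), p = NA_real_)
    edges <- edges[abs(edges$weight) > 0.05, ]
    net <- merge_networks(list(edges),
                          stats::setNames(rep("gene", n), ids),
                          score_min = 0, p_max = NULL)
    expect_equal(eigenvector_centrality(net, node_universe = ids),
                 centrality_brute(net, node_universe = ids),
                 tolerance = 1e-6)
  }
})

test_that("differential_centrality: identical graphs, star hub, antisymmetry", {
  kinds <- c(stats::setNames(rep("gene", 5), paste0("g", 1:5)),
             hubC = "cytokine")
  star <- data.frame(u = "hubC", v = paste0("g", 1:5), weight = 0.9,
                     p = NA_real_)
  net_star <- merge_networks(list(star), kinds, score_min = 0.4,
                             p_max = NULL)
  cent <- eigenvector_centrality(net_star)
  expect_equal(cent[["hubC"]], 1)
  expect_true(all(cent[paste0("g", 1:5)] < 1))

  same <- differential_centrality(list(HIV = net_star, HIV_AS = net_star))
  expect_equal(same$delta, rep(0, nrow(same)))

  empty <- merge_networks(list(), kinds)
  expect_warning(
    dc <- differential_centrality(list(HIV = empty, HIV_AS = net_star)),
    "no edges")
  expect_equal(dc$node[1], "hubC")
  expect_equal(dc$delta[1], 1)
  flip <- suppressWarnings(
    differential_centrality(list(HIV = net_star, HIV_AS = empty)))
  expect_equal(sort(flip$delta), sort(-dc$delta))
})

test_that("GraphML export writes node attributes", {
  kinds <- c(a = "gene", b = "mirna", c = "cytokine")
  el <- data.frame(u = c("a", "b"), v = c("b", "c"),
                   weight = c(0.7, -0.6), p = NA_real_)
  net <- detect_communities(
    merge_networks(list(el), kinds, score_min = 0.4, p_max = NULL))
  dc <- differential_centrality(list(HIV = net, HIV_AS = net))
  tmp <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, tmp, centrality = dc)
  g <- igraph::read_graph(tmp, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_true("delta" %in% igraph::vertex_attr_names(g))
  expect_true("community" %in% igraph::vertex_attr_names(g))
})
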