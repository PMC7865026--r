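test_that("aggregate_target_predictions counts distinct algorithms", {
  raw <- data.frame(
    mirna = c("m1", "m1", "m1", "m2", "m2", "m3"),
    gene = c("gA", "gA", "gB", "gC", "gC", "gD"),
    algorithm = c("diana", "miranda", "targetscan", "pictar", "pictar",
                  "mirdb"))
  agg <- aggregate_target_predictions(raw)
  expect_equal(agg$support[agg$mirna == "m1" & agg$gene == "gA"], 2L)
  expect_false(any(agg$mirna == "m1" & agg$gene == "gB"))  # support 1
  expect_false(any(agg$mirna == "m2"))  # duplicate same algorithm = 1
  # row-order invariance
  shuf <- raw[sample(nrow(raw)), ]
  expect_equal(aggregate_target_predictions(shuf), agg)
  # support monotone when an algorithm is added
  more <- rbind(raw, data.frame(mirna = "m1", gene = "gB",
                                algorithm = "mirdb"))
  agg2 <- aggregate_target_predictions(more, min_support = 1)
  agg1 <- aggregate_target_predictions(raw, min_support = 1)
  merged <- merge(agg1, agg2, by = c("mirna", "gene"))
  expect_true(all(merged$support.y >= merged$support.x))

  expect_error(aggregate_target_predictions(
    data.frame(mirna = "m", gene = "g", algorithm = "magic")), "magic")
})

test_that("anticorrelation_filter keeps significant negative pairs and nests", {
  set.seed(42)
  n <- 12
  mir <- c(rnorm(n, 6, 1))
  tgt_strong <- 8 - mir + rnorm(n, 0, 0.15)     # r near -1
  tgt_mild <- 8 - 0.3 * mir + rnorm(n, 0, 0.9)  # weak negative
  tgt_pos <- 2 + mir + rnorm(n, 0, 0.1)         # strongly positive
  me <- toy_normalized(matrix(mir, 1, n, dimnames = list("m1", paste0("s", 1:n))))
  ge <- toy_normalized(rbind(gNeg = tgt_strong, gMild = tgt_mild,
                             gPos = tgt_pos))
  colnames(ge$values) <- paste0("s", 1:n)
  ge <- expression_matrix(ge$values, rep("HIV", n), kind = "normalized")
  targets <- data.frame(mirna = "m1", gene = c("gNeg", "gMild", "gPos"),
                        support = 3L)
  out <- anticorrelation_filter(targets, me, ge)
  expect_true("gNeg" %in% out$gene)
  expect_false("gPos" %in% out$gene)
  expect_true(all(out$r <= -0.5 & out$p < 0.05))

  strict <- anticorrelation_filter(targets, me, ge, r_max = -0.5, p_max = 0.05)
  loose <- anticorrelation_filter(targets, me, ge, r_max = -0.4, p_max = 0.10)
  expect_true(all(paste(strict$mirna, strict$gene) %in%
                  paste(loose$mirna, loose$gene)))

  small <- subset_expression(me, samples = paste0("s", 1:3))
  expect_error(anticorrelation_filter(targets, small, ge), ">= 4")
})

test_that("lda_discriminant_genes ranks a perfect separator first and is invariant", {
  set.seed(8)
  n <- 12
  labels <- rep(c("HIV", "HIV_AS"), each = 6)
  m <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:n)))
  m["g05", ] <- ifelse(labels == "HIV", 0, 10) + rnorm(n, 0, 0.05)
  expr <- expression_matrix(m, labels, kind = "normalized")
  sel <- lda_discriminant_genes(expr, labels, k = 5)
  expect_equal(sel$ranked$gene[1], "g05")
  expect_true(sel$separated)

  # permuting gene order: identical selected set
  perm <- sample(rownames(m))
  expr_p <- expression_matrix(m[perm, ], labels, kind = "normalized")
  expect_setequal(lda_discriminant_genes(expr_p, labels, k = 5)$selected,
                  sel$selected)

  # affine rescaling of one gene leaves the ranking unchanged
  m2 <- m
  m2["g11", ] <- m2["g11", ] * 40 + 3
  sel2 <- lda_discriminant_genes(
    expression_matrix(m2, labels, kind = "normalized"), labels, k = 5)
  expect_equal(sel2$ranked$gene, sel$ranked$gene)
  expect_equal(abs(sel2$ranked$std_coef), abs(sel$ranked$std_coef),
               tolerance = 1e-8)

  expect_error(lda_discriminant_genes(expr, rep(c("a", "b", "c"), 4)),
               "two label values")
})

test_that("spearman correlation matches rank-then-pearson oracle, stars map p", {
  x <- c(1, 2, 2, 3, 5, 5)      # ties on both sides
  y <- c(2.5, 1.0, 3.0, 3.0, 6.2, 5.9)
  o <- pearson_brute(rank(x), rank(y))
  got <- plaquenet:::spearman_test(x, y)
  expect_equal(got[[1]], o$r, tolerance = 1e-12)
  expect_equal(got[["p"]], o$p, tolerance = 1e-12)

  mono <- plaquenet:::spearman_test(1:8, (1:8)^3)
  expect_equal(mono[[1]], 1)

  grid <- c(1e-5, 9e-4, 1e-3, 4e-3, 4.9e-3, 5e-3, 0.0499, 0.05, 0.2, NA)
  expect_equal(significance_stars(grid),
               c("***", "***", "**", "**", "**", "*", "*", "", "", ""))
})

test_that("mirna_cytokine_correlation builds the starred table", {
  set.seed(12)
  n <- 8
  mir <- matrix(rnorm(2 * n, 5), 2, n,
                dimnames = list(c("m1", "m2"), paste0("s", 1:n)))
  mir["m1", ] <- sort(mir["m1", ])
  me <- expression_matrix(mir, rep("HIV", n), kind = "normalized")
  pv <- cbind(up = exp(sort(rnorm(n))), rnd = exp(rnorm(n)))
  rownames(pv) <- paste0("s", 1:n)
  ct <- mirna_cytokine_correlation(me, cytokine_panel(pv))
  expect_equal(nrow(ct), 4)
  expect_equal(ct$rho[ct$mirna == "m1" & ct$analyte == "up"], 1)
  expect_equal(ct$stars[ct$mirna == "m1" & ct$analyte == "up"], "***")
})

test_that("fold_change_quadrants assigns quadrants with the null boundary", {
  de_a <- data.frame(feature = c("g1", "g2", "g3", "g4"),
                     log2fc = c(1, 0, -2, 1.5))
  de_b <- data.frame(feature = c("g1", "g2", "g3"),
                     log2fc = c(-1, 0, 3))
  q <- fold_change_quadrants(de_a, de_b, c("g1", "g2", "g3", "g4"))
  expect_equal(q$table$quadrant, c("up/down", "null", "down/up", "missing"))
  expect_equal(q$counts[["up/down"]], 1L)
  expect_equal(q$counts[["null"]], 1L)
  expect_equal(sum(q$counts), 3L)  # missing excluded
})
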