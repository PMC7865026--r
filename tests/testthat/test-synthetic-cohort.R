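test_that("cohort_config validates dimensions and effect signs", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(n_genes = 0), "positive integer")
  expect_error(cohort_config(nb_dispersion = 0), "> 0")
  expect_error(cohort_config(mirna_repression_slope = 0.5), "< 0")
  expect_error(cohort_config(n_mirnas = 10, n_de_mirnas_up = 6,
                             n_de_mirnas_down = 4), "too many")
  expect_error(cohort_config(n_genes = 100), "too small")
})

test_that("simulate_cohort is deterministic and dimensions are bookkept", {
  cfg <- cohort_config(seed = 404)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$mrna$values, b2$mrna$values)
  expect_identical(b1$mirna$values, b2$mirna$values)
  expect_identical(b1$cytokines$values, b2$cytokines$values)
  expect_identical(b1$truth, b2$truth)

  cfg2 <- cohort_config(n_per_group = 6, n_genes = 500, seed = 1)
  b <- simulate_cohort(cfg2)
  expect_equal(dim(b$mrna$values), c(500L, 24L))
  expect_equal(dim(b$mirna$values), c(150L, 12L))
  expect_equal(sort(unique(unname(b$mrna$sample_group))),
               c("AS", "CTRL", "HIV", "HIV_AS"))
  expect_equal(sort(unique(unname(b$mirna$sample_group))),
               c("HIV", "HIV_AS"))
  # sample identifiers consistent across blocks
  expect_true(all(colnames(b$mirna$values) %in% colnames(b$mrna$values)))
  expect_true(all(unique(b$cytokines$replicate_of) %in%
                  colnames(b$mrna$values)))
  # truth references only existing features
  expect_true(all(b$truth$de_genes$gene %in% rownames(b$mrna$values)))
  expect_true(all(b$truth$repressor$targets %in% rownames(b$mrna$values)))
  expect_true(all(c(b$truth$de_mirnas_up, b$truth$de_mirnas_down) %in%
                  rownames(b$mirna$values)))
  expect_true(b$truth$hub$cytokine %in% colnames(b$cytokines$values))
})

test_that("plant_mirna_de shifts the planted group means and only those", {
  cfg <- cohort_config(seed = 17)
  b <- simulate_cohort(cfg)
  expect_length(c(b$truth$de_mirnas_up, b$truth$de_mirnas_down), 12)

  # lfc = 0 reproduces the unshifted counts exactly, regardless of how
  # many features are nominated
  b0a <- plant_mirna_de(b, 3, 9, 0)
  b0b <- plant_mirna_de(b, 5, 2, 0)
  expect_identical(b0a$mirna$values, b0b$mirna$values)

  # re-planting with the config's lfc reproduces the original bundle
  b1 <- plant_mirna_de(b, cfg$n_de_mirnas_up, cfg$n_de_mirnas_down,
                       cfg$planted_lfc)
  expect_identical(b1$mirna$values, b$mirna$values)

  # planted shift visible in group means (log2 scale, generous margin)
  as_cols <- names(b$mirna$sample_group)[b$mirna$sample_group == "HIV_AS"]
  hiv_cols <- setdiff(colnames(b$mirna$values), as_cols)
  up <- b$truth$de_mirnas_up
  ratio <- log2(rowMeans(b$mirna$values[up, as_cols, drop = FALSE]) + 1) -
    log2(rowMeans(b$mirna$values[up, hiv_cols, drop = FALSE]) + 1)
  expect_true(all(ratio > 0.5))

  expect_error(plant_mirna_de(b, 100, 100, 1), "too many")
})

test_that("write_fixture_bundle round-trips through the package readers", {
  dir <- withr::local_tempdir()
  b <- simulate_cohort(cohort_config(n_genes = 400, n_mirnas = 40,
                                     seed = 99))
  manifest <- write_fixture_bundle(b, dir)
  expect_setequal(manifest$file,
                  c("mrna_counts.tsv", "mirna_counts.tsv", "cytokines.tsv",
                    "tf_targets.gmt", "mir_predictions.tsv",
                    "sample_groups.tsv", "truth.json"))
  expect_equal(manifest$rows[manifest$file == "mrna_counts.tsv"], 400)
  expect_equal(manifest$cols[manifest$file == "mrna_counts.tsv"], 24)

  back <- read_fixture_bundle(dir)
  expect_equal(back$mrna$values, b$mrna$values)
  expect_equal(back$mirna$values, b$mirna$values)
  expect_equal(back$mrna$sample_group, b$mrna$sample_group)
  expect_equal(unname(back$cytokines$values), unname(b$cytokines$values),
               tolerance = 1e-12)
  expect_equal(back$tf_targets, b$tf_targets)
  expect_equal(back$mir_predictions, b$mir_predictions)
  expect_equal(back$truth$repressor$targets, b$truth$repressor$targets)

  # byte-identical files under the same config + seed
  dir2 <- withr::local_tempdir()
  write_fixture_bundle(simulate_cohort(cohort_config(n_genes = 400,
                                                     n_mirnas = 40,
                                                     seed = 99)), dir2)
  for (f in manifest$file) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("planted miR-target pairs anticorrelate in expectation", {
  cors <- vapply(seed_stream(23, 25), function(s) {
    b <- simulate_cohort(cohort_config(n_genes = 500, seed = s))
    nm <- normalize_vst(b$mirna)
    ng <- normalize_vst(subset_expression(
      b$mrna, samples = colnames(b$mirna$values)))
    mean(vapply(b$truth$repressor$targets, function(g)
      cor(nm$values[b$truth$repressor$mirna, ], ng$values[g, ]),
      numeric(1)))
  }, numeric(1))
  expect_lt(mean(cors), 0)
  expect_true(mean(cors < 0) > 0.9)
})
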