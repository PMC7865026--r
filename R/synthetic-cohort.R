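# Synthetic multi-omic cohort generator. Emulates the statistical
# structure the analysis assumes: NB counts with high inter-individual
# dispersion over a 4-group design (CTRL / AS / HIV / HIV_AS), a miRNA
# assay restricted to the two HIV groups, log-normal cytokines measured
# in technical duplicate, a planted TF-activity axis correlated with one
# cytokine, a planted miRNA that represses its targets on the log scale,
# planted discriminant genes between the HIV groups, and a cytokine hub
# wired into the mRNA block of the HIV_AS group only. Every planted
# effect is recorded in a truth manifest so recovery can be scored.

#' Configuration for the synthetic cohort
#'
#' @param n_per_group samples per group (4 groups: CTRL, AS, HIV,
#'   HIV_AS).
#' @param n_genes,n_mirnas,n_cytokines,n_tfs block dimensions.
#' @param nb_dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param planted_lfc log2 effect size of planted group-effect features.
#' @param n_de_mirnas_up,n_de_mirnas_down planted DE miRNAs, higher in
#'   HIV_AS / higher in HIV (defaults 3 and 9).
#' @param n_de_genes planted discriminant genes between HIV_AS and HIV
#'   (default 27).
#' @param tf_axis_strength correlation in [0, 1] between the planted
#'   TF's latent activity and its partner cytokine (default 0.8).
#' @param mirna_repression_slope negative log-log slope linking the
#'   planted repressor miRNA to its target genes (default -1).
#' @param targets_per_tf target-set size per TF (default 30).
#' @param n_mir_targets planted repressed targets (default 10).
#' @param n_hub_genes genes wired to the HIV_AS-specific cytokine hub
#'   (default 15).
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 6, n_genes = 1000, n_mirnas = 150,
                          n_cytokines = 29, n_tfs = 10,
                          nb_dispersion = 0.2, planted_lfc = 2,
                          n_de_mirnas_up = 3, n_de_mirnas_down = 9,
                          n_de_genes = 27, tf_axis_strength = 0.8,
                          mirna_repression_slope = -1, targets_per_tf = 30,
                          n_mir_targets = 10, n_hub_genes = 15, seed = 1) {
  cfg <- list(n_per_group = n_per_group, n_genes = n_genes,
              n_mirnas = n_mirnas, n_cytokines = n_cytokines,
              n_tfs = n_tfs, nb_dispersion = nb_dispersion,
              planted_lfc = planted_lfc, n_de_mirnas_up = n_de_mirnas_up,
              n_de_mirnas_down = n_de_mirnas_down, n_de_genes = n_de_genes,
              tf_axis_strength = tf_axis_strength,
              mirna_repression_slope = mirna_repression_slope,
              targets_per_tf = targets_per_tf,
              n_mir_targets = n_mir_targets, n_hub_genes = n_hub_genes,
              seed = seed)
  dims <- c("n_per_group", "n_genes", "n_mirnas", "n_cytokines", "n_tfs")
  for (d in dims)
    if (!is.numeric(cfg[[d]]) || cfg[[d]] < 1 || cfg[[d]] != round(cfg[[d]]))
      stop("`", d, "` must be a positive integer")
  if (cfg$nb_dispersion <= 0) stop("`nb_dispersion` must be > 0")
  if (cfg$mirna_repression_slope >= 0)
    stop("`mirna_repression_slope` must be < 0")
  if (cfg$tf_axis_strength < 0 || cfg$tf_axis_strength > 1)
    stop("`tf_axis_strength` must be in [0, 1]")
  if (cfg$n_de_mirnas_up + cfg$n_de_mirnas_down + 1 > cfg$n_mirnas)
    stop("too many planted miRNAs for `n_mirnas`")
  need <- cfg$n_tfs * cfg$targets_per_tf + cfg$n_de_genes +
    cfg$n_mir_targets + cfg$n_hub_genes
  if (need > cfg$n_genes)
    stop("`n_genes` too small for the planted structure (need >= ", need, ")")
  if (cfg$n_cytokines < 2) stop("need >= 2 cytokines for the planted axes")
  structure(cfg, class = "cohort_config")
}

rnb <- function(u, mu, alpha) {
  stats::qnbinom(u, size = 1 / alpha, mu = mu)
}

#' Simulate a full multi-omic cohort
#'
#' @param config a [cohort_config()].
#' @return An object of class `fixture_bundle`: list with `mrna` and
#'   `mirna` count [expression_matrix()] objects, `cytokines` (a
#'   [cytokine_panel()] with duplicate wells), `tf_targets` (gene-set
#'   list), `mir_predictions` (raw prediction table with columns
#'   `mirna`, `gene`, `algorithm`), `truth` (planted-effect record),
#'   `config`, and generator internals used by [plant_mirna_de()].
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  groups <- c("CTRL", "AS", "HIV", "HIV_AS")
  samples <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(cfg$n_per_group))))
  grp <- stats::setNames(rep(groups, each = cfg$n_per_group), samples)
  n <- length(samples)
  hiv_samples <- samples[grp %in% c("HIV", "HIV_AS")]
  as_flag <- grp == "HIV_AS"

  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  mirnas <- sprintf("miR-%04d", seq_len(cfg$n_mirnas))
  cytokines <- sprintf("CYT%02d", seq_len(cfg$n_cytokines))

  # ---- gene bookkeeping: disjoint planted sets ----
  pool <- sample(genes)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  tf_targets <- stats::setNames(
    lapply(seq_len(cfg$n_tfs), function(i) sort(take(cfg$targets_per_tf))),
    sprintf("TF%02d", seq_len(cfg$n_tfs)))
  de_genes <- take(cfg$n_de_genes)
  mir_targets <- take(cfg$n_mir_targets)
  hub_genes <- take(cfg$n_hub_genes)

  # ---- latent subject structure ----
  # Inter-individual variability is deliberately strong and structured,
  # the regime the spTFscore is designed for:
  #  * an "overall transcription" axis with gene-specific sensitivities
  #    (the typical sensitivity 1 is absorbed by size factors; the
  #    residual spread survives normalization and dominates PC1 of
  #    every TF target slice without reaching 50% of its variance);
  #  * three weaker cell-composition-like axes with random gene
  #    loadings, which dilute PC1's variance share without polluting
  #    the PC2 coordinate the score reads.
  # Genes carrying the other planted mechanisms (group effects, miRNA
  # repression, the cytokine hub) get unit global sensitivity and no
  # composition loading so each mechanism stays separately
  # identifiable.
  special <- c(de_genes, mir_targets, hub_genes)
  global_factor <- 1.25 * pmax(pmin(stats::rnorm(n), 2), -2)
  global_load <- 1 + sample(c(-0.8, 0.8), cfg$n_genes, replace = TRUE)
  global_load[match(special, genes)] <- 1
  n_comp <- 3
  comp_factors <- matrix(stats::rnorm(n * n_comp), n, n_comp)
  comp_loads <- matrix(stats::rnorm(cfg$n_genes * n_comp, 0, 0.55),
                       cfg$n_genes, n_comp)
  comp_loads[match(special, genes), ] <- 0
  lib_mrna <- 2^stats::runif(n, -1, 1)              # 4-fold library range
  # Every TF has an activity latent with a right-skewed dysregulation
  # magnitude (multiplicative biology) and a random direction, driving a
  # mixed-sign target program (activated and repressed targets) -- which
  # keeps TF axes non-collinear with the all-positive global axis. The
  # latents are standardized so `tf_amp` sets the axis size on the log2
  # scale. The spTFscore measures |deviation| of the target program, so
  # the planted association couples one cytokine to the planted TF's
  # dysregulation *magnitude*.
  tf_amp <- 0.85
  tf_magnitude <- matrix(stats::rlnorm(n * cfg$n_tfs, 0, 1),
                         n, cfg$n_tfs)
  tf_sign <- matrix(sample(c(-1, 1), n * cfg$n_tfs, replace = TRUE),
                    n, cfg$n_tfs)
  # subject-side latents are decorrelated from the global/composition
  # factors (finite-sample chance correlations would otherwise rotate
  # part of the TF axis into PC1, which the score discards)
  other_axes <- cbind(global_factor, comp_factors)
  tf_latents <- vapply(seq_len(cfg$n_tfs), function(i) {
    raw <- tf_sign[, i] * tf_magnitude[, i]
    as.vector(scale(stats::resid(stats::lm(raw ~ other_axes))))
  }, numeric(n))
  tf_activity <- as.vector(scale(tf_magnitude[, 1]))
  hub_latent <- ifelse(as_flag, stats::rnorm(n, 0, 1.4), 0)

  # ---- mRNA log2 means ----
  base_gene <- stats::runif(cfg$n_genes, 2.5, 9)
  # planted-mechanism genes are drawn well-expressed: detecting their
  # effects is only defined away from the count floor
  base_gene[match(special, genes)] <- stats::runif(length(special), 6, 8.5)
  logmu <- matrix(base_gene, cfg$n_genes, n,
                  dimnames = list(genes, samples))
  bio_sd <- ifelse(genes %in% special, 0.2, 0.45)
  logmu <- logmu + global_load %o% global_factor +
    comp_loads %*% t(comp_factors) +
    matrix(stats::rnorm(cfg$n_genes * n, 0, bio_sd), cfg$n_genes, n)
  for (i in seq_len(cfg$n_tfs)) {
    tgt <- tf_targets[[i]]
    dirs <- rep(c(1, -1), length.out = length(tgt)) *
      stats::runif(length(tgt), 0.6, 1.4)
    # gene-side program orthogonal to the slice's global/composition
    # loadings, for the same reason as the latent decorrelation above
    gi <- match(tgt, genes)
    basis <- cbind(global_load[gi] - 1, comp_loads[gi, ])
    dirs <- stats::resid(stats::lm(dirs ~ basis))
    dirs <- dirs / sqrt(mean(dirs^2)) * sqrt(1.05)
    logmu[tgt, ] <- logmu[tgt, ] + (tf_amp * dirs) %o% tf_latents[, i]
  }
  # planted discriminant genes: +lfc in HIV_AS vs HIV; the first 15 are
  # additionally lower in AS than CTRL, the rest higher (quadrant truth)
  logmu[de_genes, as_flag] <- logmu[de_genes, as_flag] + cfg$planted_lfc
  n_dd <- min(15, cfg$n_de_genes)
  as_dir <- c(rep(-1, n_dd), rep(1, cfg$n_de_genes - n_dd))
  logmu[de_genes, grp == "AS"] <- logmu[de_genes, grp == "AS"] +
    as_dir * cfg$planted_lfc
  # repressor miRNA drives its targets down on the log scale (HIV groups)
  rep_latent <- stats::setNames(stats::rnorm(length(hiv_samples), 0, 1.8),
                                hiv_samples)
  logmu[mir_targets, hiv_samples] <- logmu[mir_targets, hiv_samples] +
    rep(1, length(mir_targets)) %o%
    (cfg$mirna_repression_slope * rep_latent)
  # HIV_AS-specific cytokine hub: shared latent across its gene partners
  hub_load <- stats::runif(cfg$n_hub_genes, 1.0, 1.4)
  logmu[hub_genes, ] <- logmu[hub_genes, ] + hub_load %o% hub_latent

  mu_mrna <- sweep(2^logmu, 2, lib_mrna, "*")
  u_mrna <- matrix(stats::runif(length(mu_mrna)), nrow(mu_mrna))
  mrna_counts <- matrix(rnb(u_mrna, mu_mrna, cfg$nb_dispersion),
                        nrow(mu_mrna), dimnames = dimnames(mu_mrna))

  # ---- miRNA block (HIV groups only) ----
  lib_mirna <- stats::setNames(2^stats::runif(length(hiv_samples), -1, 1),
                               hiv_samples)
  base_mir <- stats::runif(cfg$n_mirnas, 4, 9)
  base_mir[cfg$n_de_mirnas_up + cfg$n_de_mirnas_down + 1] <- 8  # repressor
  logmu_mir <- matrix(base_mir, cfg$n_mirnas, length(hiv_samples),
                      dimnames = list(mirnas, hiv_samples))
  rep_mirna <- mirnas[cfg$n_de_mirnas_up + cfg$n_de_mirnas_down + 1]
  logmu_mir[rep_mirna, ] <- logmu_mir[rep_mirna, ] + rep_latent
  mu0_mir <- sweep(2^logmu_mir, 2, lib_mirna, "*")
  u_mir <- matrix(stats::runif(length(mu0_mir)), nrow(mu0_mir))

  # ---- cytokines (all subjects, duplicate wells) ----
  base_cyt <- stats::runif(cfg$n_cytokines, log(20), log(500))
  logc <- matrix(base_cyt, cfg$n_cytokines, n,
                 dimnames = list(cytokines, samples)) +
    matrix(0.6 * stats::rnorm(cfg$n_cytokines * n), cfg$n_cytokines, n)
  # planted TF-cytokine axis at correlation tf_axis_strength
  rho <- cfg$tf_axis_strength
  logc[1, ] <- base_cyt[1] +
    0.6 * (rho * tf_activity + sqrt(1 - rho^2) * stats::rnorm(n))
  # hub cytokine tracks the HIV_AS-only latent closely
  logc[2, ] <- base_cyt[2] + 1.0 * hub_latent + 0.15 * stats::rnorm(n)
  dup_noise <- matrix(stats::rnorm(2 * cfg$n_cytokines * n, 0, 0.1),
                      2 * n, cfg$n_cytokines)
  subj_rep <- rep(samples, each = 2)
  wells <- paste0(subj_rep, "_rep", rep(1:2, n))
  cyt_values <- exp(t(logc)[subj_rep, , drop = FALSE] + dup_noise)
  rownames(cyt_values) <- wells
  panel <- cytokine_panel(cyt_values,
                          replicate_of = stats::setNames(subj_rep, wells))

  # ---- target predictions: planted pairs plus decoys ----
  pred_rows <- data.frame(
    mirna = rep(rep_mirna, 3 * length(mir_targets)),
    gene = rep(mir_targets, each = 3),
    algorithm = rep(c("diana", "miranda", "targetscan"),
                    length(mir_targets)),
    stringsAsFactors = FALSE)
  de_mirs <- mirnas[seq_len(cfg$n_de_mirnas_up + cfg$n_de_mirnas_down)]
  n_decoy <- 150
  decoy <- data.frame(
    mirna = sample(de_mirs, n_decoy, replace = TRUE),
    gene = sample(genes, n_decoy, replace = TRUE),
    algorithm = sample(MIR_ALGORITHMS, n_decoy, replace = TRUE),
    stringsAsFactors = FALSE)
  extra <- decoy[stats::runif(n_decoy) < 0.5, , drop = FALSE]
  if (nrow(extra))
    extra$algorithm <- vapply(extra$algorithm, function(a)
      sample(setdiff(MIR_ALGORITHMS, a), 1), character(1))
  pred <- rbind(pred_rows, decoy, extra)
  rownames(pred) <- NULL

  truth <- list(
    de_genes = data.frame(gene = de_genes,
                          lfc_hiv_as_vs_hiv = cfg$planted_lfc,
                          lfc_as_vs_ctrl = as_dir * cfg$planted_lfc,
                          stringsAsFactors = FALSE),
    de_mirnas_up = character(0), de_mirnas_down = character(0),
    tf_cytokine = list(tf = names(tf_targets)[1], cytokine = cytokines[1]),
    repressor = list(mirna = rep_mirna, targets = mir_targets,
                     slope = cfg$mirna_repression_slope),
    hub = list(cytokine = cytokines[2], genes = hub_genes))

  bundle <- structure(
    list(mrna = expression_matrix(mrna_counts, grp, kind = "counts"),
         mirna = NULL, cytokines = panel, tf_targets = tf_targets,
         mir_predictions = pred, truth = truth, config = cfg,
         internals = list(mu0_mir = mu0_mir, u_mir = u_mir,
                          mirna_groups = grp[hiv_samples])),
    class = "fixture_bundle")
  plant_mirna_de(bundle, cfg$n_de_mirnas_up, cfg$n_de_mirnas_down,
                 cfg$planted_lfc)
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(paste0("<fixture_bundle> mRNA %d x %d, miRNA %d x %d, ",
                     "%d cytokines, %d TFs\n"),
              nrow(x$mrna$values), ncol(x$mrna$values),
              nrow(x$mirna$values), ncol(x$mirna$values),
              ncol(x$cytokines$values), length(x$tf_targets)))
  invisible(x)
}

#' Re-plant the differentially expressed miRNAs
#'
#' Regenerates the miRNA counts from the bundle's stored baseline means
#' and uniform draws, shifting the first `n_up` miRNAs up and the next
#' `n_down` down by `lfc` (log2) in the HIV_AS group relative to HIV.
#' Because the uniform draws are fixed, `lfc = 0` reproduces the
#' unshifted counts exactly, and re-planting is deterministic.
#'
#' @param bundle a `fixture_bundle`.
#' @param n_up,n_down numbers of up-/down-planted miRNAs.
#' @param lfc log2 shift magnitude.
#' @return The bundle with updated `mirna` counts and truth record.
#' @export
plant_mirna_de <- function(bundle, n_up, n_down, lfc) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  cfg <- bundle$config
  if (n_up + n_down + 1 > cfg$n_mirnas)
    stop("too many planted miRNAs for `n_mirnas` (the repressor needs a slot)")
  mu <- bundle$internals$mu0_mir
  grp <- bundle$internals$mirna_groups
  as_cols <- names(grp)[grp == "HIV_AS"]
  mirnas <- rownames(mu)
  up <- mirnas[seq_len(n_up)]
  down <- if (n_down > 0) mirnas[n_up + seq_len(n_down)] else character(0)
  mu[up, as_cols] <- mu[up, as_cols] * 2^lfc
  mu[down, as_cols] <- mu[down, as_cols] * 2^(-lfc)
  counts <- matrix(rnb(bundle$internals$u_mir, mu, cfg$nb_dispersion),
                   nrow(mu), dimnames = dimnames(mu))
  bundle$mirna <- expression_matrix(counts, grp, kind = "counts")
  bundle$truth$de_mirnas_up <- up
  bundle$truth$de_mirnas_down <- down
  bundle
}

#' Write a fixture bundle to plain-text files
#'
#' Emits TSV count tables, a cytokine TSV with duplicate wells, a GMT of
#' TF target sets, the raw prediction table, sample-group maps and a
#' JSON truth manifest; all files round-trip losslessly through the
#' package readers.
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @return A manifest `data.frame` (file, rows, cols), invisibly also
#'   written as `manifest.json`.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  fp <- function(x) file.path(dir, x)
  write_expression_table(bundle$mrna, fp("mrna_counts.tsv"))
  write_expression_table(bundle$mirna, fp("mirna_counts.tsv"))
  write_cytokine_panel(bundle$cytokines, fp("cytokines.tsv"))
  write_gene_sets(bundle$tf_targets, fp("tf_targets.gmt"))
  utils::write.table(bundle$mir_predictions, fp("mir_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  all_groups <- c(bundle$mrna$sample_group,
                  bundle$mirna$sample_group)
  all_groups <- all_groups[!duplicated(names(all_groups))]
  utils::write.table(
    data.frame(sample = names(all_groups), group = unname(all_groups)),
    fp("sample_groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- data.frame(
    file = c("mrna_counts.tsv", "mirna_counts.tsv", "cytokines.tsv",
             "tf_targets.gmt", "mir_predictions.tsv", "sample_groups.tsv",
             "truth.json"),
    rows = c(nrow(bundle$mrna$values), nrow(bundle$mirna$values),
             nrow(bundle$cytokines$values), length(bundle$tf_targets),
             nrow(bundle$mir_predictions), length(all_groups), NA),
    cols = c(ncol(bundle$mrna$values), ncol(bundle$mirna$values),
             ncol(bundle$cytokines$values), NA, 3, 2, NA),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, fp("manifest.json"), digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle directory back
#'
#' @param dir a directory written by [write_fixture_bundle()].
#' @return A list with `mrna`, `mirna`, `cytokines`, `tf_targets`,
#'   `mir_predictions`, `truth`.
#' @export
read_fixture_bundle <- function(dir) {
  fp <- function(x) file.path(dir, x)
  gm <- utils::read.table(fp("sample_groups.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  group_map <- stats::setNames(gm$group, gm$sample)
  list(mrna = read_expression_table(fp("mrna_counts.tsv"), group_map),
       mirna = read_expression_table(fp("mirna_counts.tsv"), group_map),
       cytokines = read_cytokine_panel(fp("cytokines.tsv")),
       tf_targets = read_gene_sets(fp("tf_targets.gmt")),
       mir_predictions = utils::read.table(fp("mir_predictions.tsv"),
                                           header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE),
       truth = jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE))
}
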