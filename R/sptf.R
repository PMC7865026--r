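# Single-person transcription-factor activity scores. For each TF, PCA is
# run on the subjects-by-target-genes slice of the normalized expression
# matrix (genes mean-centered, not variance-scaled: the amplitude of the
# target program is the signal). PC1 tends to track inter-individual
# variation in overall transcription, so the score deliberately starts at
# PC2:
#
#   score_j = sqrt( sum_{i=2..m} s_{ji}^2 * v_i )
#
# where s_{ji} is subject j's unweighted score on PC i (the U*Sigma
# coordinate), v_i the fraction of variance explained by PC i, and m the
# first PC at which cumulative variance (counting from PC1) reaches 50%.
# When m = 1 the sum is empty and the score is 0. Per-gene contributions
# use the unit-norm loadings w:
#
#   weight_g = sqrt( sum_{i=2..m} w_{gi}^2 * v_i ) / (1 - v_1)
#
# reported as percentages summing to 100 per TF.

#' Single-person TF activity scores
#'
#' @param expr an [expression_matrix()] of kind `"normalized"` with >= 3
#'   samples (subjects).
#' @param tf_targets named list mapping TF name to its target gene IDs.
#' @param cum_var cumulative-variance threshold defining `m`
#'   (default 0.5).
#' @return An object of class `sptf_result`: list with `scores` (subject
#'   x TF matrix), `m` (named integer per TF), `variance_fractions`,
#'   `pc_scores`, `gene_weights` (per-TF named percentage vectors) and
#'   `skipped` (TFs with < 2 expressed targets).
#' @export
sptf_scores <- function(expr, tf_targets, cum_var = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$kind != "normalized")
    stop("sptf_scores() expects normalized expression")
  n <- ncol(expr$values)
  if (n < 3) stop("need >= 3 subjects")
  stopifnot(is.list(tf_targets), !is.null(names(tf_targets)))
  subjects <- colnames(expr$values)
  tfs <- names(tf_targets)
  scores <- matrix(NA_real_, n, length(tfs),
                   dimnames = list(subjects, tfs))
  m_per_tf <- stats::setNames(rep(NA_integer_, length(tfs)), tfs)
  vfrac <- pc_scores <- gene_weights <- stats::setNames(
    vector("list", length(tfs)), tfs)
  skipped <- character(0)
  for (tf in tfs) {
    genes <- intersect(tf_targets[[tf]], rownames(expr$values))
    if (length(genes) < 2) {
      warning("TF ", tf, " has < 2 expressed target genes; skipped")
      skipped <- c(skipped, tf)
      next
    }
    x <- t(expr$values[genes, , drop = FALSE])  # subjects x genes
    xc <- scale(x, center = TRUE, scale = FALSE)
    sv <- svd(xc)
    ev <- sv$d^2
    if (sum(ev) <= 1e-12 * length(genes)) {
      # zero-variance slice: no axis to score on
      scores[, tf] <- 0
      m_per_tf[[tf]] <- 1L
      vfrac[[tf]] <- NA_real_
      pc_scores[[tf]] <- matrix(0, n, 1, dimnames = list(subjects, "PC1"))
      gene_weights[[tf]] <- stats::setNames(rep(0, length(genes)), genes)
      next
    }
    npc <- sum(sv$d > sv$d[1] * 1e-12)
    v <- ev[seq_len(npc)] / sum(ev[seq_len(npc)])
    s <- sv$u[, seq_len(npc), drop = FALSE] %*%
      diag(sv$d[seq_len(npc)], npc)          # unweighted PC scores
    w <- sv$v[, seq_len(npc), drop = FALSE]  # unit-norm loadings
    dimnames(s) <- list(subjects, paste0("PC", seq_len(npc)))
    dimnames(w) <- list(genes, paste0("PC", seq_len(npc)))
    m <- which(cumsum(v) >= cum_var - 1e-12)[1]
    m_per_tf[[tf]] <- as.integer(m)
    vfrac[[tf]] <- v
    pc_scores[[tf]] <- s
    if (m < 2) {
      scores[, tf] <- 0
      gene_weights[[tf]] <- stats::setNames(rep(0, length(genes)), genes)
    } else {
      idx <- 2:m
      scores[, tf] <- sqrt(as.vector(s[, idx, drop = FALSE]^2 %*% v[idx]))
      raw <- sqrt(as.vector(w[, idx, drop = FALSE]^2 %*% v[idx])) /
        (1 - v[1])
      gene_weights[[tf]] <- stats::setNames(100 * raw / sum(raw), genes)
    }
  }
  structure(list(scores = scores, m = m_per_tf, variance_fractions = vfrac,
                 pc_scores = pc_scores, gene_weights = gene_weights,
                 skipped = skipped, cum_var = cum_var),
            class = "sptf_result")
}

#' @export
print.sptf_result <- function(x, ...) {
  cat(sprintf("<sptf_result> %d subjects x %d TFs (m: %s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(range(x$m, na.rm = TRUE), collapse = "-")))
  invisible(x)
}

#' Per-TF gene weight table
#'
#' Long-format view of the per-gene percentage contributions already
#' computed by [sptf_scores()].
#'
#' @param result an `sptf_result`.
#' @return `data.frame` with columns `tf`, `gene`, `weight_pct`.
#' @export
tf_gene_weights <- function(result) {
  stopifnot(inherits(result, "sptf_result"))
  rows <- lapply(names(result$gene_weights), function(tf) {
    w <- result$gene_weights[[tf]]
    if (is.null(w)) return(NULL)
    data.frame(tf = tf, gene = names(w), weight_pct = unname(w),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Pearson correlation with the exact t-distribution p-value; returns NAs
# for constant input (r is then undefined, not 0).
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(c(r = r, p = 0, n = n))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Correlate TF activity scores with plasma cytokine levels
#'
#' Pearson correlation of each TF's score vector against each analyte
#' over the subjects common to both, with a two-sided t-test p-value.
#' The significance flag marks raw p < 0.05 (no multiplicity correction,
#' matching the starred-heatmap convention); set `adjust = TRUE` for an
#' additional BH column.
#'
#' @param result an `sptf_result`.
#' @param panel a collapsed [cytokine_panel()] (one row per subject).
#' @param adjust add a BH-adjusted p column (default `FALSE`).
#' @return `data.frame` with columns `tf`, `analyte`, `r`, `p`, `n`,
#'   `significant` (and `padj` when requested).
#' @export
correlate_scores_with_cytokines <- function(result, panel, adjust = FALSE) {
  stopifnot(inherits(result, "sptf_result"), inherits(panel, "cytokine_panel"))
  if (!is.null(panel$replicate_of))
    stop("collapse technical replicates before correlating")
  common <- intersect(rownames(result$scores), rownames(panel$values))
  if (length(common) < 4) stop("need >= 4 subjects shared with the panel")
  tfs <- colnames(result$scores)
  analytes <- colnames(panel$values)
  grid <- expand.grid(tf = tfs, analyte = analytes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_m <- t(mapply(function(tf, an)
    pearson_test(result$scores[common, tf], panel$values[common, an]),
    grid$tf, grid$analyte))
  out <- data.frame(grid, r = stats_m[, "r"], p = stats_m[, "p"],
                    n = as.integer(stats_m[, "n"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- !is.na(out$p) & out$p < 0.05
  if (adjust) out$padj <- bh_adjust(out$p)
  out
}
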