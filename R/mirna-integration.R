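# Integration of miRNA expression with predicted targets: support
# aggregation across prediction algorithms, expression anticorrelation
# filtering, discriminant gene selection by regularized LDA, and
# miRNA-cytokine Spearman correlation.

#' Canonical miRNA target-prediction algorithms
#' @export
MIR_ALGORITHMS <- c("diana", "miranda", "targetscan", "pictar", "mirdb")

#' Aggregate raw target predictions into supported pairs
#'
#' Counts, for each (miRNA, gene) pair, how many distinct prediction
#' algorithms support it, and keeps pairs reaching `min_support` (the
#' usual at-least-2-of-5 rule). Listing a pair twice under the same
#' algorithm counts once. Output is sorted by miRNA then gene, so it is
#' invariant to input row order.
#'
#' @param raw `data.frame` with columns `mirna`, `gene`, `algorithm`.
#' @param min_support minimum number of supporting algorithms (default 2).
#' @param algorithms the declared algorithm universe; unknown labels in
#'   `raw` are an error.
#' @return `data.frame` with columns `mirna`, `gene`, `support`.
#' @export
aggregate_target_predictions <- function(raw, min_support = 2,
                                         algorithms = MIR_ALGORITHMS) {
  stopifnot(is.data.frame(raw),
            all(c("mirna", "gene", "algorithm") %in% colnames(raw)))
  unknown <- setdiff(unique(raw$algorithm), algorithms)
  if (length(unknown))
    stop("unknown prediction algorithm(s): ", paste(unknown, collapse = ", "))
  key <- paste(raw$mirna, raw$gene, sep = "\r")
  support <- tapply(raw$algorithm, key, function(a) length(unique(a)))
  parts <- strsplit(names(support), "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, "", 1),
                    gene = vapply(parts, `[`, "", 2),
                    support = as.integer(support),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter predicted targets by expression anticorrelation
#'
#' For each supported (miRNA, gene) pair, correlates the miRNA's and the
#' gene's normalized expression over the samples assayed on both
#' platforms and keeps pairs with a significant negative correlation
#' (default r <= -0.5 and p < 0.05, Pearson; Spearman available).
#'
#' @param targets output of [aggregate_target_predictions()].
#' @param mirna_expr,mrna_expr normalized [expression_matrix()] objects
#'   sharing >= 4 samples.
#' @param r_max correlation ceiling (default -0.5).
#' @param p_max p-value ceiling (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The retained rows of `targets` with `r` and `p` columns added.
#'   Pairs whose miRNA or gene is not in the matrices are dropped.
#' @export
anticorrelation_filter <- function(targets, mirna_expr, mrna_expr,
                                   r_max = -0.5, p_max = 0.05,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(mirna_expr, "expression_matrix"),
            inherits(mrna_expr, "expression_matrix"))
  common <- intersect(colnames(mirna_expr$values), colnames(mrna_expr$values))
  if (length(common) < 4) stop("need >= 4 samples shared by both assays")
  keep <- targets$mirna %in% rownames(mirna_expr$values) &
    targets$gene %in% rownames(mrna_expr$values)
  out <- targets[keep, , drop = FALSE]
  if (!nrow(out)) {
    out$r <- numeric(0); out$p <- numeric(0)
    return(out)
  }
  st <- t(mapply(function(mir, g) {
    x <- mirna_expr$values[mir, common]
    y <- mrna_expr$values[g, common]
    if (method == "spearman") spearman_test(x, y) else pearson_test(x, y)
  }, out$mirna, out$gene))
  out$r <- st[, 1]
  out$p <- st[, "p"]
  out <- out[!is.na(out$r) & out$r <= r_max & out$p < p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discriminant target genes by regularized LDA
#'
#' Two-class linear discriminant analysis on a genes-by-samples slice of
#' normalized expression, with the pooled within-class covariance shrunk
#' toward its diagonal, `S = (1 - lambda) * Sw + lambda * diag(Sw)`, so
#' the fit is defined when genes outnumber samples. Genes are ranked by
#' the absolute standardized discriminant coefficient
#' `|beta_g| * sd_within(g)` (invariant to per-gene rescaling) and the
#' top `k` are selected. The selected set is re-fit and every sample
#' projected on the resulting axis; `separated` flags whether the two
#' groups' projections do not overlap.
#'
#' @param expr normalized [expression_matrix()] restricted to candidate
#'   genes (e.g. the anticorrelation-filtered targets).
#' @param labels binary sample labels (named by sample or in column
#'   order); exactly two levels, each with >= 3 samples.
#' @param k number of genes to select (default 27).
#' @param lambda diagonal shrinkage weight in [0, 1] (default 0.5).
#' @return An object of class `lda_selection`: list with `ranked`
#'   (`data.frame` gene/coef/std_coef ordered by rank), `selected`,
#'   `projection` (named per-sample values on the selected-gene axis),
#'   `separated`, `k`, `lambda`.
#' @export
lda_discriminant_genes <- function(expr, labels, k = 27, lambda = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- t(expr$values)  # samples x genes
  if (is.null(names(labels))) {
    if (length(labels) != nrow(x)) stop("one label per sample required")
    names(labels) <- rownames(x)
  }
  labels <- as.character(labels[rownames(x)])
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("exactly two label values required, got ",
                             length(lev))
  if (any(table(labels) < 3)) stop("need >= 3 samples per class")
  fit_axis <- function(xm) {
    mu1 <- colMeans(xm[labels == lev[1], , drop = FALSE])
    mu2 <- colMeans(xm[labels == lev[2], , drop = FALSE])
    c1 <- stats::cov(xm[labels == lev[1], , drop = FALSE])
    c2 <- stats::cov(xm[labels == lev[2], , drop = FALSE])
    n1 <- sum(labels == lev[1]); n2 <- sum(labels == lev[2])
    sw <- ((n1 - 1) * c1 + (n2 - 1) * c2) / (n1 + n2 - 2)
    s <- (1 - lambda) * sw + lambda * diag(diag(sw), ncol(xm))
    # guard genes with zero within-class variance
    diag(s) <- pmax(diag(s), 1e-12)
    beta <- solve(s, mu2 - mu1)
    list(beta = beta, sd_within = sqrt(pmax(diag(sw), 0)))
  }
  fit <- fit_axis(x)
  std_coef <- fit$beta * fit$sd_within
  ord <- order(-abs(std_coef), colnames(x))
  ranked <- data.frame(gene = colnames(x)[ord],
                       coef = unname(fit$beta[ord]),
                       std_coef = unname(std_coef[ord]),
                       stringsAsFactors = FALSE)
  k_eff <- min(k, nrow(ranked))
  selected <- ranked$gene[seq_len(k_eff)]
  refit <- fit_axis(x[, selected, drop = FALSE])
  proj <- drop(x[, selected, drop = FALSE] %*% refit$beta)
  names(proj) <- rownames(x)
  r1 <- range(proj[labels == lev[1]])
  r2 <- range(proj[labels == lev[2]])
  separated <- r1[2] < r2[1] || r2[2] < r1[1]
  structure(list(ranked = ranked, selected = selected, projection = proj,
                 separated = separated, k = k_eff, lambda = lambda,
                 levels = lev),
            class = "lda_selection")
}

#' @export
print.lda_selection <- function(x, ...) {
  cat(sprintf("<lda_selection> %d of %d genes (%s vs %s); separated: %s\n",
              x$k, nrow(x$ranked), x$levels[1], x$levels[2], x$separated))
  invisible(x)
}

# Spearman rho via average ranks, p from the t approximation (the same
# approximation cor.test uses in the presence of ties).
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  pearson_test(rank(x), rank(y))
}

#' Map a p-value to significance stars
#'
#' `***` p < 0.001, `**` p < 0.005, `*` p < 0.05, `""` otherwise; the
#' most extreme applicable tier wins.
#'
#' @param p numeric vector.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.005] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' Spearman correlation of miRNAs with cytokines
#'
#' Rank correlation of every miRNA against every analyte over the shared
#' samples, with stars per [significance_stars()].
#'
#' @param mirna_expr normalized [expression_matrix()].
#' @param panel collapsed [cytokine_panel()]; row names must match the
#'   expression sample IDs.
#' @return `data.frame` with columns `mirna`, `analyte`, `rho`, `p`, `n`,
#'   `stars`.
#' @export
mirna_cytokine_correlation <- function(mirna_expr, panel) {
  stopifnot(inherits(mirna_expr, "expression_matrix"),
            inherits(panel, "cytokine_panel"))
  if (!is.null(panel$replicate_of))
    stop("collapse technical replicates before correlating")
  common <- intersect(colnames(mirna_expr$values), rownames(panel$values))
  if (length(common) < 4) stop("need >= 4 shared samples")
  grid <- expand.grid(mirna = rownames(mirna_expr$values),
                      analyte = colnames(panel$values),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  st <- t(mapply(function(mir, an)
    spearman_test(mirna_expr$values[mir, common], panel$values[common, an]),
    grid$mirna, grid$analyte))
  out <- data.frame(grid, rho = st[, 1], p = st[, "p"],
                    n = as.integer(st[, "n"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$stars <- significance_stars(out$p)
  out
}

#' Cross-contrast fold-change quadrants
#'
#' Pairs each gene's log2 fold change in one contrast (e.g. HIV_AS vs
#' HIV) with its fold change in another (e.g. AS vs CTRL) and assigns the
#' sign quadrant; a fold change of exactly 0 in either contrast is
#' assigned to `"null"` rather than a direction. Genes missing from
#' either result list are recorded with quadrant `"missing"` and excluded
#' from the counts.
#'
#' @param de_a,de_b data.frames from [nb_wald_test()].
#' @param genes genes to tabulate.
#' @return List with `table` (gene, lfc_a, lfc_b, quadrant) and `counts`
#'   (named vector over up/up, up/down, down/up, down/down, null).
#' @export
fold_change_quadrants <- function(de_a, de_b, genes) {
  la <- stats::setNames(de_a$log2fc, de_a$feature)[genes]
  lb <- stats::setNames(de_b$log2fc, de_b$feature)[genes]
  quadrant <- ifelse(is.na(la) | is.na(lb), "missing",
              ifelse(la == 0 | lb == 0, "null",
                     paste(ifelse(la > 0, "up", "down"),
                           ifelse(lb > 0, "up", "down"), sep = "/")))
  tab <- data.frame(gene = genes, lfc_a = unname(la), lfc_b = unname(lb),
                    quadrant = quadrant, stringsAsFactors = FALSE)
  lv <- c("up/up", "up/down", "down/up", "down/down", "null")
  counts <- stats::setNames(
    as.integer(table(factor(quadrant[quadrant != "missing"], levels = lv))),
    lv)
  list(table = tab, counts = counts)
}
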