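# Negative-binomial Wald tests for two-group contrasts. The model is the
# standard RNA-seq NB with variance mu + alpha * mu^2, log link and
# size-factor offsets; per-feature dispersions come from a method-of-
# moments estimate shrunk halfway toward a mean-dispersion trend. This is
# a deliberately plain NB test: no LFC shrinkage, no independent
# filtering, no outlier replacement.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. Implemented directly (rather than delegating)
#' so it can be property-tested against an independent brute-force
#' definition; ties and `NA`s behave like the conventional step-up
#' transform, with `NA` p-values left `NA` and excluded from the ranking.
#'
#' @param p numeric vector of p-values (may contain `NA`).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  n <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(n / (n:1) * pv[o]))[ro]
  out
}

#' Method-of-moments dispersion estimates
#'
#' Per-feature NB dispersion alpha (variance mu + alpha mu^2) from the
#' within-group residual variance of size-factor-normalized counts,
#' shrunk with weight 0.5 toward a `a0 + a1/mean` trend fitted across
#' features. Features whose within-group residual variance is exactly
#' zero carry no evidence of overdispersion and keep alpha = 0.
#'
#' @param mat an [expression_matrix()] of counts.
#' @param groups optional group labels to define the design; defaults to
#'   the matrix's own `sample_group`. Every group must have >= 2 samples.
#' @return Named numeric vector of dispersions, one per feature.
#' @export
estimate_dispersions <- function(mat, groups = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$kind != "counts") stop("dispersions are estimated from raw counts")
  if (is.null(groups)) groups <- mat$sample_group
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2))
    stop("group(s) with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  sf <- size_factors(mat$values)
  q <- sweep(mat$values, 2, sf, "/")
  inv_sf <- 1 / sf
  glevels <- names(tab)
  n <- ncol(q)
  ss_res <- numeric(nrow(q))
  mean_term <- numeric(nrow(q))  # E[residual SS] component due to Poisson noise
  sq_term <- numeric(nrow(q))    # coefficient of alpha in E[residual SS]
  for (g in glevels) {
    idx <- groups == g
    ng <- sum(idx)
    qg <- q[, idx, drop = FALSE]
    mu_g <- rowMeans(qg)
    ss_res <- ss_res + rowSums((qg - mu_g)^2)
    mean_term <- mean_term + (ng - 1) * mu_g * mean(inv_sf[idx])
    sq_term <- sq_term + (ng - 1) * mu_g^2
  }
  alpha_raw <- ifelse(sq_term > 0, pmax(0, (ss_res - mean_term) / sq_term), 0)
  mu_all <- rowMeans(q)
  # trend alpha(mu) = a0 + a1/mu over informative features
  use <- alpha_raw > 0 & mu_all > 0
  if (sum(use) >= 3) {
    fit <- stats::lm(alpha_raw[use] ~ I(1 / mu_all[use]))
    a <- pmax(0, stats::coef(fit))
    trend <- a[1] + a[2] / pmax(mu_all, 1e-8)
  } else {
    trend <- rep(mean(alpha_raw[use]), nrow(q))
    trend[is.na(trend)] <- 0
  }
  alpha <- ifelse(ss_res == 0, 0, 0.5 * alpha_raw + 0.5 * trend)
  stats::setNames(pmax(alpha, 0), rownames(mat$values))
}

# Single-group NB mean fit on the log scale with size-factor offsets.
# Returns the MLE beta (natural log of the group mean) and the Fisher
# information at the optimum.
fit_nb_group <- function(y, sf, alpha) {
  if (sum(y) == 0) return(c(beta = NA_real_, info = NA_real_))
  beta <- log(sum(y) / sum(sf))
  for (it in 1:50) {
    mu <- sf * exp(beta)
    score <- sum((y - mu) / (1 + alpha * mu))
    fisher <- sum(mu / (1 + alpha * mu))
    if (fisher <= 0) break
    step <- score / fisher
    step <- max(min(step, 5), -5)
    beta <- beta + step
    if (abs(step) < 1e-10) break
  }
  mu <- sf * exp(beta)
  c(beta = beta, info = sum(mu / (1 + alpha * mu)))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits a per-feature NB GLM with log link and size-factor offsets, one
#' mean per group, and tests the log2 fold change `contrast[1]` vs
#' `contrast[2]` with a Wald statistic. P-values are two-sided normal;
#' adjustment is Benjamini-Hochberg over the features that could be
#' tested. Features with zero counts in either group get `NA` statistics.
#' Output rows keep the input feature order; ranking ties in the BH step
#' are resolved deterministically.
#'
#' @param mat an [expression_matrix()] of counts.
#' @param contrast character vector of two group labels,
#'   `c(numerator, denominator)` of the fold change.
#' @param dispersions optional named vector of per-feature alphas;
#'   computed by [estimate_dispersions()] over the two contrast groups
#'   when absent.
#' @return `data.frame` with columns `feature`, `base_mean`, `log2fc`,
#'   `se`, `stat`, `p`, `padj`.
#' @export
nb_wald_test <- function(mat, contrast, dispersions = NULL) {
  stopifnot(inherits(mat, "expression_matrix"), length(contrast) == 2)
  unknown <- setdiff(contrast, unique(mat$sample_group))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  if (mat$kind != "counts") stop("nb_wald_test() requires raw counts")
  sub <- subset_expression(mat, samples = samples_in_groups(mat, contrast))
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(sub)
  if (is.null(names(dispersions)))
    names(dispersions) <- rownames(sub$values)
  sf <- size_factors(sub$values)
  g1 <- samples_in_groups(sub, contrast[1])
  g2 <- samples_in_groups(sub, contrast[2])
  feats <- rownames(sub$values)
  res <- data.frame(feature = feats,
                    base_mean = rowMeans(sweep(sub$values, 2, sf, "/")),
                    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, padj = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(feats)) {
    a <- dispersions[[feats[i]]]
    f1 <- fit_nb_group(sub$values[i, g1], sf[g1], a)
    f2 <- fit_nb_group(sub$values[i, g2], sf[g2], a)
    if (any(is.na(c(f1, f2)))) next
    lfc <- (f1[["beta"]] - f2[["beta"]]) / log(2)
    se <- sqrt(1 / f1[["info"]] + 1 / f2[["info"]]) / log(2)
    res$log2fc[i] <- lfc
    res$se[i] <- se
    res$stat[i] <- lfc / se
    res$p[i] <- 2 * stats::pnorm(-abs(lfc / se))
  }
  res$padj <- bh_adjust(res$p)
  res
}

#' Filter differential-expression results by padj and |log2fc|
#'
#' @param results data.frame from [nb_wald_test()].
#' @param padj_max keep features with `padj < padj_max`.
#' @param lfc_min keep features with `abs(log2fc) > lfc_min`.
#' @return The retained rows of `results`.
#' @export
apply_de_thresholds <- function(results, padj_max, lfc_min = 0) {
  stopifnot(is.data.frame(results))
  keep <- !is.na(results$padj) & results$padj < padj_max &
    abs(results$log2fc) > lfc_min
  results[keep, , drop = FALSE]
}
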