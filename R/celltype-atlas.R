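# Cell-type miRNA atlas: summarize a labeled multi-cell-type miRNA
# compendium (the layout of the 450-sample, ten-population blood-cell
# reference) by per-miRNA discretization into B levels and per-cell-type
# medians of the discrete levels.

#' Number of discretization bins from per-cell-type sample counts
#'
#' `B = ceiling(max(n)^(1/3))` where `n` are the per-cell-type sample
#' counts. Computed with a small tolerance so exact cubes do not round up
#' through floating-point error.
#'
#' @param samples_per_type named integer vector (or map) of sample counts
#'   per cell type, all >= 1.
#' @return Integer number of bins.
#' @export
n_bins <- function(samples_per_type) {
  n <- unlist(samples_per_type)
  if (!length(n)) stop("empty sample-count map")
  if (any(n < 1)) stop("sample counts must be >= 1")
  as.integer(ceiling(max(n)^(1/3) - 1e-9))
}

#' Discretize abundances into equal-width levels per miRNA
#'
#' Each miRNA's values are cut into `B` equal-width bins spanning its own
#' [min, max] across all samples, mapped to levels 1..B with higher
#' levels meaning higher expression; a value on an interior bin edge
#' belongs to the upper bin, and a constant miRNA maps entirely to
#' level 1.
#'
#' @param mat normalized [expression_matrix()] (samples labeled by cell
#'   type).
#' @param B integer >= 1.
#' @return Integer matrix of levels, same dimnames as the input values.
#' @export
discretize_abundances <- function(mat, B) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!is.numeric(B) || length(B) != 1 || B < 1 || B != round(B))
    stop("`B` must be a single integer >= 1")
  v <- mat$values
  out <- matrix(1L, nrow(v), ncol(v), dimnames = dimnames(v))
  if (B == 1) return(out)
  for (i in seq_len(nrow(v))) {
    rng <- range(v[i, ])
    if (rng[1] == rng[2]) next
    edges <- seq(rng[1], rng[2], length.out = B + 1)
    out[i, ] <- findInterval(v[i, ], edges, all.inside = TRUE)
  }
  out
}

#' Per-cell-type median expression levels
#'
#' Median of the discrete levels of each miRNA within each cell type;
#' even-sized groups take the lower of the two middle values so the
#' output stays on the integer 1..B scale.
#'
#' @param levels integer matrix from [discretize_abundances()].
#' @param cell_labels cell-type label per sample (named by sample or in
#'   column order).
#' @param B the number of bins the levels were built with (metadata).
#' @return An object of class `celltype_atlas`: list with `levels`
#'   (miRNA x cell-type integer matrix), `n_bins`, `n_samples_per_type`.
#' @export
celltype_medians <- function(levels, cell_labels, B = max(levels)) {
  stopifnot(is.matrix(levels))
  if (is.null(names(cell_labels))) {
    if (length(cell_labels) != ncol(levels))
      stop("one cell-type label per sample required")
    names(cell_labels) <- colnames(levels)
  }
  missing <- setdiff(colnames(levels), names(cell_labels))
  if (length(missing))
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "))
  cell_labels <- as.character(cell_labels[colnames(levels)])
  types <- sort(unique(cell_labels))
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  out <- vapply(types, function(ty)
    apply(levels[, cell_labels == ty, drop = FALSE], 1, lower_median),
    numeric(nrow(levels)))
  out <- matrix(as.integer(out), nrow(levels), length(types),
                dimnames = list(rownames(levels), types))
  structure(list(levels = out, n_bins = as.integer(B),
                 n_samples_per_type = table(cell_labels)),
            class = "celltype_atlas")
}

#' @export
print.celltype_atlas <- function(x, ...) {
  cat(sprintf("<celltype_atlas> %d miRNAs x %d cell types, %d levels\n",
              nrow(x$levels), ncol(x$levels), x$n_bins))
  invisible(x)
}

#' Drop miRNAs with very low counts in every sample
#'
#' Retains miRNAs with at least one sample at or above `min_count`
#' (default 3, the compendium's very-low-count exclusion).
#'
#' @param mat an [expression_matrix()] of counts.
#' @param min_count integer (default 3).
#' @return Filtered `expression_matrix`.
#' @export
low_expression_filter <- function(mat, min_count = 3) {
  filter_low_counts(mat, min_count)
}

#' Build a discretized cell-type atlas from a counts compendium
#'
#' Convenience wrapper chaining [low_expression_filter()],
#' [normalize_vst()], [n_bins()] on the label counts,
#' [discretize_abundances()] and [celltype_medians()].
#'
#' @param counts an [expression_matrix()] of counts whose sample groups
#'   are cell-type labels.
#' @param min_count low-count exclusion threshold (default 3).
#' @return A `celltype_atlas`.
#' @export
build_celltype_atlas <- function(counts, min_count = 3) {
  filtered <- low_expression_filter(counts, min_count)
  norm <- normalize_vst(filtered)
  B <- n_bins(table(counts$sample_group))
  lv <- discretize_abundances(norm, B)
  celltype_medians(lv, counts$sample_group, B = B)
}
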