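#' Expression matrix with sample metadata
#'
#' Lightweight container for a feature-by-sample abundance matrix plus the
#' per-sample group label used throughout the pipeline. `kind` records
#' whether the values are raw counts or normalized (log-scale) abundances;
#' several downstream operations insist on one or the other.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry unique row and column names.
#' @param sample_group character/factor vector of group labels, one per
#'   sample, either named by sample or in column order. Typical labels are
#'   `CTRL`, `AS`, `HIV`, `HIV_AS`, or blood-cell-type names for the
#'   miRNA compendium.
#' @param kind `"counts"` (non-negative integers) or `"normalized"`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `sample_group` (named character) and `kind`.
#' @export
expression_matrix <- function(values, sample_group,
                              kind = c("counts", "normalized")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("`values` must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries")
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("counts must be non-negative integers")
  }
  sample_group <- stats::setNames(as.character(sample_group),
                                  names(sample_group))
  if (is.null(names(sample_group))) {
    if (length(sample_group) != ncol(values))
      stop("`sample_group` must have one label per sample")
    names(sample_group) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(sample_group))
  if (length(missing))
    stop("samples missing a group label: ", paste(missing, collapse = ", "))
  sample_group <- sample_group[colnames(values)]
  structure(list(values = values, sample_group = sample_group, kind = kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$kind))
  tab <- table(x$sample_group)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by features and/or samples
#'
#' @param x an [expression_matrix()].
#' @param features,samples character or index vectors; `NULL` keeps all.
#' @return An `expression_matrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, x$sample_group[colnames(v)], kind = x$kind)
}

#' Samples belonging to given groups
#' @param x an [expression_matrix()].
#' @param groups character vector of group labels.
#' @return Character vector of sample IDs.
#' @export
samples_in_groups <- function(x, groups) {
  stopifnot(inherits(x, "expression_matrix"))
  unknown <- setdiff(groups, unique(x$sample_group))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  names(x$sample_group)[x$sample_group %in% groups]
}

#' Cytokine/chemokine panel container
#'
#' Holds a sample-by-analyte matrix of bead-array abundances. Before
#' replicate collapse the rows are technical replicate wells and
#' `replicate_of` maps each well to its subject; after
#' [collapse_technical_replicates()] there is exactly one row per subject
#' and `replicate_of` is `NULL`.
#'
#' @param values numeric matrix, samples (wells or subjects) in rows,
#'   analytes in columns; strictly positive.
#' @param replicate_of optional named character vector mapping each row to
#'   a subject ID; `NULL` means rows are already subjects.
#' @return An object of class `cytokine_panel`.
#' @export
cytokine_panel <- function(values, replicate_of = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (sample) and column (analyte) names")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("panel values must be finite and > 0")
  if (!is.null(replicate_of)) {
    replicate_of <- stats::setNames(as.character(replicate_of),
                                    names(replicate_of))
    missing <- setdiff(rownames(values), names(replicate_of))
    if (length(missing))
      stop("wells missing a subject assignment: ",
           paste(missing, collapse = ", "))
    replicate_of <- replicate_of[rownames(values)]
  } else if (anyDuplicated(rownames(values))) {
    stop("duplicate subject rows in a collapsed panel")
  }
  structure(list(values = values, replicate_of = replicate_of),
            class = "cytokine_panel")
}

#' @export
print.cytokine_panel <- function(x, ...) {
  what <- if (is.null(x$replicate_of)) "subjects" else "replicate wells"
  cat(sprintf("<cytokine_panel> %d %s x %d analytes\n",
              nrow(x$values), what, ncol(x$values)))
  invisible(x)
}
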