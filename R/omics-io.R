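# Readers, writers and the count-level preprocessing shared by every
# downstream module: low-count filters, size-factor normalization and
# technical-replicate collapse of the cytokine panel.

#' Read a feature-by-sample expression table
#'
#' Expects a TSV with a header row of sample IDs and the feature ID in the
#' first column, the layout used for both sequencing count tables and the
#' cell-type compendium.
#'
#' @param path file path.
#' @param group_map named character vector mapping every sample ID in the
#'   header to its group label.
#' @param kind `"counts"` or `"normalized"`.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, group_map,
                                  kind = c("counts", "normalized")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expected a feature ID column plus >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 2, is.numeric))
    stop("non-numeric values in column(s): ",
         paste(colnames(df)[-1][bad], collapse = ", "))
  }
  rownames(m) <- ids
  missing <- setdiff(colnames(m), names(group_map))
  if (length(missing))
    stop("samples absent from group_map: ", paste(missing, collapse = ", "))
  expression_matrix(m, group_map[colnames(m)], kind = kind)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: header of sample IDs, feature IDs
#' in a first column named `feature`.
#'
#' @param mat an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  df <- data.frame(feature = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop features never reaching a minimum count
#'
#' A feature is excluded iff its count is below `min_count` in every
#' sample, i.e. retained iff its maximum count across samples reaches
#' `min_count`. This is the reading of the "fewer than N reads in all
#' samples" exclusion used for both the mRNA/miRNA tables (N = 10) and the
#' blood-cell compendium (N = 3). Feature order and the sample set are
#' preserved, and the filter is idempotent.
#'
#' @param mat an [expression_matrix()] of counts.
#' @param min_count integer >= 1.
#' @return Filtered `expression_matrix`.
#' @export
filter_low_counts <- function(mat, min_count) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$kind != "counts") stop("filter_low_counts() requires raw counts")
  if (!is.numeric(min_count) || length(min_count) != 1 || min_count < 1)
    stop("`min_count` must be a single integer >= 1")
  keep <- apply(mat$values, 1, max) >= min_count
  m <- mat$values[keep, , drop = FALSE]
  expression_matrix(m, mat$sample_group, kind = "counts")
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed against a geometric-mean pseudo
#' reference over the features with all-positive counts.
#'
#' @param counts numeric matrix of counts (features x samples).
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) == 0)) {
    bad <- colnames(counts)[colSums(counts) == 0]
    stop("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no feature has positive counts in every sample; cannot form a reference")
  sf <- apply(counts, 2, function(cnt)
    exp(stats::median(log(cnt[usable]) - log_geo[usable])))
  names(sf) <- colnames(counts)
  sf
}

#' Variance-stabilizing normalization of counts
#'
#' Divides each sample by its median-of-ratios size factor and takes
#' log2(x + 1). This is a deterministic, monotone stand-in for the
#' dispersion-fit VST of the usual RNA-seq toolchain: ranks and all
#' rank-based downstream steps are unaffected by the difference. Size
#' factors are attached as the `size_factors` attribute.
#'
#' @param mat an [expression_matrix()] of counts with >= 2 samples.
#' @return An `expression_matrix` of kind `"normalized"`.
#' @export
normalize_vst <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$kind != "counts") stop("normalize_vst() requires raw counts")
  if (ncol(mat$values) < 2) stop("need >= 2 samples")
  sf <- size_factors(mat$values)
  norm <- log2(sweep(mat$values, 2, sf, "/") + 1)
  out <- expression_matrix(norm, mat$sample_group, kind = "normalized")
  attr(out, "size_factors") <- sf
  out
}

#' Collapse technical replicates of the cytokine panel
#'
#' Each subject's analyte value becomes the geometric mean of its
#' replicate wells (the standard treatment of Luminex technical
#' duplicates). Zeros, which make the geometric mean degenerate, are first
#' replaced by half the smallest positive value of that analyte.
#'
#' @param panel a [cytokine_panel()] with `replicate_of` set.
#' @return A collapsed `cytokine_panel`, one row per subject, sorted by
#'   subject ID.
#' @export
collapse_technical_replicates <- function(panel) {
  stopifnot(inherits(panel, "cytokine_panel"))
  if (is.null(panel$replicate_of))
    return(panel)
  v <- panel$values
  for (a in seq_len(ncol(v))) {
    zero <- v[, a] <= 0
    if (any(zero)) {
      pos <- v[!zero, a]
      if (!length(pos)) stop("analyte ", colnames(v)[a], " is all zero")
      v[zero, a] <- min(pos) / 2
    }
  }
  subjects <- sort(unique(panel$replicate_of))
  out <- matrix(NA_real_, length(subjects), ncol(v),
                dimnames = list(subjects, colnames(v)))
  for (s in subjects) {
    rows <- v[panel$replicate_of == s, , drop = FALSE]
    if (!nrow(rows)) stop("subject ", s, " has no replicate rows")
    out[s, ] <- exp(colMeans(log(rows)))
  }
  cytokine_panel(out, replicate_of = NULL)
}

#' Read a cytokine panel TSV
#'
#' Layout: columns `subject`, `replicate`, then one column per analyte;
#' one row per replicate well.
#'
#' @param path file path.
#' @return A [cytokine_panel()] with `replicate_of` mapping wells to
#'   subjects.
#' @export
read_cytokine_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject", "replicate") %in% colnames(df)))
    stop("cytokine TSV must have 'subject' and 'replicate' columns")
  wells <- paste(df$subject, df$replicate, sep = "_rep")
  m <- as.matrix(df[, setdiff(colnames(df), c("subject", "replicate")),
                    drop = FALSE])
  rownames(m) <- wells
  cytokine_panel(m, replicate_of = stats::setNames(as.character(df$subject),
                                                   wells))
}

#' Write a cytokine panel TSV
#' @param panel a [cytokine_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytokine_panel <- function(panel, path) {
  stopifnot(inherits(panel, "cytokine_panel"))
  if (is.null(panel$replicate_of)) {
    subject <- rownames(panel$values)
    replicate <- rep(1L, nrow(panel$values))
  } else {
    subject <- unname(panel$replicate_of)
    replicate <- stats::ave(seq_along(subject), subject,
                            FUN = seq_along)
  }
  df <- data.frame(subject = subject, replicate = replicate, panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#' Duplicate members within a set are stored once; duplicate set names and
#' empty sets are rejected.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (e.g. TF -> target genes).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3 || !any(nzchar(parts[-(1:2)])))
      stop("line ", i, ": gene set with no members")
    nm <- parts[[1]]
    if (nm %in% names(sets)) stop("line ", i, ": duplicate set name ", nm)
    sets[[nm]] <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
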