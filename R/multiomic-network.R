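# Integrated cytokine/miRNA/mRNA association network. Block pairs are
# scored with a sparse two-block PLS: per component, the leading
# singular-vector pair of the cross-covariance is hard-thresholded to the
# top fraction of loadings, block variates and reconstructions are
# accumulated, and the association score of a feature pair is the
# correlation of their reconstructions across samples. Edges are
# filtered on |score| and a permutation p-value, merged into a typed
# graph per group, partitioned into communities, and compared between
# groups by max-normalized eigenvector centrality.

# Sparse PLS decomposition of two sample-by-feature blocks. The
# reconstruction of a feature uses the *sparse* weight vectors
# (variate times thresholded weight), so features never selected by any
# component have an identically zero reconstruction and produce no
# association -- the sparsity does the feature selection, as in the
# usual sparse-PLS integration tools. Deflation uses the standard
# regression loadings.
spls_reconstruct <- function(xa, xb, n_components, keep_fraction) {
  xa <- scale(xa, center = TRUE, scale = FALSE)
  xb <- scale(xb, center = TRUE, scale = FALSE)
  hat_a <- matrix(0, nrow(xa), ncol(xa), dimnames = dimnames(xa))
  hat_b <- matrix(0, nrow(xb), ncol(xb), dimnames = dimnames(xb))
  keep_n <- function(p) max(1L, ceiling(keep_fraction * p))
  for (h in seq_len(n_components)) {
    m <- crossprod(xa, xb)
    if (sum(abs(m)) < 1e-12) break
    sv <- svd(m, nu = 1, nv = 1)
    w <- sparsify(drop(sv$u), keep_n(ncol(xa)))
    c_ <- sparsify(drop(sv$v), keep_n(ncol(xb)))
    t_ <- drop(xa %*% w)
    u_ <- drop(xb %*% c_)
    if (sum(t_^2) < 1e-12 || sum(u_^2) < 1e-12) break
    hat_a <- hat_a + tcrossprod(t_, w)
    hat_b <- hat_b + tcrossprod(u_, c_)
    p_ <- drop(crossprod(xa, t_)) / sum(t_^2)
    q_ <- drop(crossprod(xb, u_)) / sum(u_^2)
    xa <- xa - tcrossprod(t_, p_)
    xb <- xb - tcrossprod(u_, q_)
  }
  list(a = hat_a, b = hat_b)
}

# keep the `keep` largest |loadings|, zero the rest, renormalize
sparsify <- function(v, keep) {
  if (keep < length(v)) {
    thr <- sort(abs(v), decreasing = TRUE)[keep]
    v[abs(v) < thr] <- 0
  }
  nv <- sqrt(sum(v^2))
  if (nv > 0) v / nv else v
}

score_from_reconstructions <- function(ha, hb) {
  sda <- apply(ha, 2, stats::sd)
  sdb <- apply(hb, 2, stats::sd)
  sc <- matrix(0, ncol(ha), ncol(hb),
               dimnames = list(colnames(ha), colnames(hb)))
  oka <- sda > 0
  okb <- sdb > 0
  if (any(oka) && any(okb))
    sc[oka, okb] <- stats::cor(ha[, oka, drop = FALSE],
                               hb[, okb, drop = FALSE])
  sc
}

#' Sparse-PLS association scores between two omic blocks
#'
#' Scores every feature pair across two blocks measured on the same
#' samples and attaches a permutation p-value obtained by permuting the
#' sample rows of the second block and recomputing the whole
#' decomposition (`n_perm` times, seeded). With univariate blocks, one
#' component and `keep_fraction = 1` the score equals the plain Pearson
#' correlation.
#'
#' @param block_a,block_b numeric matrices, samples in rows (>= 4 shared
#'   rows by name), features in columns.
#' @param n_components number of PLS components (default 2).
#' @param keep_fraction fraction of loadings retained per block and
#'   component (default 0.1; 1 disables sparsity).
#' @param n_perm permutations for the p-value (default 200; 0 skips the
#'   permutation test and leaves `p = NA`).
#' @param seed integer seed for the permutations.
#' @return `data.frame` edge list with columns `u`, `v`, `weight`, `p`.
#' @export
pairwise_spls_associations <- function(block_a, block_b, n_components = 2,
                                       keep_fraction = 0.1, n_perm = 200,
                                       seed = 1) {
  stopifnot(is.matrix(block_a), is.matrix(block_b))
  common <- intersect(rownames(block_a), rownames(block_b))
  if (length(common) < 4) stop("need >= 4 shared samples")
  xa <- block_a[common, , drop = FALSE]
  xb <- block_b[common, , drop = FALSE]
  rec <- spls_reconstruct(xa, xb, n_components, keep_fraction)
  obs <- score_from_reconstructions(rec$a, rec$b)
  pmat <- matrix(NA_real_, nrow(obs), ncol(obs))
  if (n_perm > 0) {
    # Rank-matched permutation null: the k-th largest observed |score|
    # is compared with the permutation distribution of the k-th largest
    # retained |score|. A per-pair null is useless here (a given pair is
    # rarely re-selected under permutation), and a fully pooled null
    # mixes the score distributions of different components, which
    # miscalibrates both.
    sel_obs <- as.vector(outer(apply(rec$a, 2, stats::sd) > 0,
                               apply(rec$b, 2, stats::sd) > 0, "&"))
    obs_abs <- abs(as.vector(obs))[sel_obs]
    ord <- order(obs_abs, decreasing = TRUE)
    k_obs <- length(obs_abs)
    exceed <- integer(k_obs)
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      perm <- sample(nrow(xb))
      recp <- spls_reconstruct(xa, xb[perm, , drop = FALSE],
                               n_components, keep_fraction)
      sp <- score_from_reconstructions(recp$a, recp$b)
      keep <- as.vector(outer(apply(recp$a, 2, stats::sd) > 0,
                              apply(recp$b, 2, stats::sd) > 0, "&"))
      null_sorted <- sort(abs(as.vector(sp)[keep]), decreasing = TRUE)
      if (length(null_sorted) < k_obs)
        null_sorted <- c(null_sorted,
                         rep(0, k_obs - length(null_sorted)))
      exceed <- exceed +
        (null_sorted[seq_len(k_obs)] >= obs_abs[ord] - 1e-12)
    }
    p_sel <- numeric(k_obs)
    p_sel[ord] <- (1 + exceed) / (1 + n_perm)
    pfull <- rep(NA_real_, length(sel_obs))
    pfull[sel_obs] <- p_sel
    pmat <- matrix(pfull, nrow(obs), ncol(obs))
  }
  out <- data.frame(u = rep(colnames(xa), times = ncol(xb)),
                    v = rep(colnames(xb), each = ncol(xa)),
                    weight = as.vector(obs), p = as.vector(pmat),
                    stringsAsFactors = FALSE)
  # features never selected by any component have identically zero
  # reconstructions; they carry no association
  sel <- as.vector(outer(apply(rec$a, 2, stats::sd) > 0,
                         apply(rec$b, 2, stats::sd) > 0, "&"))
  out[sel, , drop = FALSE]
}

#' Merge block-pair edge lists into a typed association network
#'
#' Keeps edges with `|weight| >= score_min` and (when a permutation
#' p-value is present and `p_max` is not `NULL`) `p < p_max`, takes the
#' union over all block pairs, resolves duplicate edges by the larger
#' absolute score, and drops isolated nodes.
#'
#' @param edge_lists list of data.frames from
#'   [pairwise_spls_associations()].
#' @param node_kinds named character vector mapping node IDs to one of
#'   `gene`, `mirna`, `cytokine`.
#' @param score_min minimum |score| (default 0.4).
#' @param p_max permutation p ceiling (default 0.05); `NULL` disables the
#'   p filter (required when the edge lists carry no p-values).
#' @return An object of class `assoc_network`: list with `nodes`
#'   (`data.frame` id/kind), `edges` (`data.frame` u/v/weight/p) and
#'   optionally `communities` after [detect_communities()].
#' @export
merge_networks <- function(edge_lists, node_kinds, score_min = 0.4,
                           p_max = 0.05) {
  stopifnot(is.list(edge_lists))
  all_edges <- do.call(rbind, edge_lists)
  if (is.null(all_edges) || !nrow(all_edges))
    return(structure(list(nodes = data.frame(id = character(0),
                                             kind = character(0)),
                          edges = data.frame(u = character(0),
                                             v = character(0),
                                             weight = numeric(0),
                                             p = numeric(0))),
                     class = "assoc_network"))
  keep <- abs(all_edges$weight) >= score_min
  if (!is.null(p_max)) {
    if (all(is.na(all_edges$p)))
      stop("edge lists carry no p-values; use p_max = NULL")
    keep <- keep & !is.na(all_edges$p) & all_edges$p < p_max
  }
  e <- all_edges[keep, , drop = FALSE]
  if (nrow(e)) {
    # canonical orientation, then keep the largest |weight| per pair
    flip <- e$u > e$v
    tmp <- e$u[flip]; e$u[flip] <- e$v[flip]; e$v[flip] <- tmp
    key <- paste(e$u, e$v, sep = "\r")
    e <- e[order(key, -abs(e$weight)), , drop = FALSE]
    e <- e[!duplicated(paste(e$u, e$v, sep = "\r")), , drop = FALSE]
    e <- e[e$u != e$v, , drop = FALSE]
    rownames(e) <- NULL
  }
  ids <- sort(unique(c(e$u, e$v)))
  unknown <- setdiff(ids, names(node_kinds))
  if (length(unknown))
    stop("nodes with no declared kind: ", paste(unknown, collapse = ", "))
  nodes <- data.frame(id = ids, kind = unname(node_kinds[ids]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = e), class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network> %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%s=%d", names(table(x$nodes$kind)),
                            table(x$nodes$kind)), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("u", "v")], directed = FALSE,
    vertices = net$nodes$id)
  igraph::E(g)$weight <- net$edges$weight
  igraph::V(g)$kind <- net$nodes$kind
  g
}

#' Community detection on an association network
#'
#' Multilevel (Louvain) modularity maximization on the absolute edge
#' weights, seeded for reproducibility.
#'
#' @param net an `assoc_network` with >= 1 node.
#' @param seed integer seed.
#' @return The network with a `communities` element (named integer
#'   vector, node -> community id).
#' @export
detect_communities <- function(net, seed = 1) {
  stopifnot(inherits(net, "assoc_network"))
  if (!nrow(net$nodes)) stop("empty graph")
  g <- as_igraph(net)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = abs(igraph::E(g)$weight))
  net$communities <- stats::setNames(as.integer(igraph::membership(cl)),
                                     igraph::V(g)$name)
  net
}

#' Eigenvector centrality on absolute edge weights
#'
#' Leading-eigenvector centrality computed per connected component (the
#' Perron vector of the component's |weight| adjacency, scaled by the
#' component's spectral radius so denser components dominate), then
#' globally normalized to a maximum of 1. Isolated nodes score 0.
#'
#' @param net an `assoc_network`.
#' @param node_universe optional node IDs the result must cover (absent
#'   nodes get 0).
#' @return Named numeric vector of centralities in [0, 1].
#' @export
eigenvector_centrality <- function(net, node_universe = NULL) {
  stopifnot(inherits(net, "assoc_network"))
  ids <- if (is.null(node_universe)) net$nodes$id else node_universe
  cent <- stats::setNames(rep(0, length(ids)), ids)
  if (!nrow(net$edges)) {
    warning("network has no edges; all centralities 0")
    return(cent)
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  adj <- abs(as.matrix(igraph::as_adjacency_matrix(
    g, attr = "weight", sparse = TRUE)))
  for (k in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) < 2) next
    a <- adj[members, members, drop = FALSE]
    es <- eigen(a, symmetric = TRUE)
    lead <- abs(es$vectors[, 1])
    cent[members] <- lead / max(lead) * abs(es$values[1])
  }
  if (max(cent) > 0) cent <- cent / max(cent)
  cent
}

#' Differential eigenvector centrality between group networks
#'
#' Computes per-group centralities over the union node set and their
#' difference `contrast[1] - contrast[2]` (by default HIV_AS minus HIV),
#' sorted by decreasing delta.
#'
#' @param net_by_group named list of `assoc_network` objects, one per
#'   group.
#' @param contrast the two group names to difference.
#' @return `data.frame` with columns `node`, `kind`, one centrality
#'   column per group (`centrality_<group>`), and `delta`.
#' @export
differential_centrality <- function(net_by_group,
                                    contrast = c("HIV_AS", "HIV")) {
  stopifnot(is.list(net_by_group), !is.null(names(net_by_group)),
            all(contrast %in% names(net_by_group)))
  universe <- sort(unique(unlist(lapply(net_by_group,
                                        function(n) n$nodes$id))))
  kinds <- unlist(lapply(net_by_group, function(n)
    stats::setNames(n$nodes$kind, n$nodes$id)))
  kinds <- kinds[!duplicated(names(kinds))]
  cents <- lapply(net_by_group, eigenvector_centrality,
                  node_universe = universe)
  out <- data.frame(node = universe, kind = unname(kinds[universe]),
                    stringsAsFactors = FALSE)
  for (g in names(net_by_group))
    out[[paste0("centrality_", g)]] <- unname(cents[[g]][universe])
  out$delta <- out[[paste0("centrality_", contrast[1])]] -
    out[[paste0("centrality_", contrast[2])]]
  out[order(-out$delta, out$node), , drop = FALSE]
}

#' Build per-group association networks from the three omic blocks
#'
#' End-to-end wrapper: for each requested group, restricts the blocks to
#' that group's samples, scores the three block pairs with
#' [pairwise_spls_associations()], and merges the edge lists.
#'
#' @param mrna,mirna normalized [expression_matrix()] objects.
#' @param panel collapsed [cytokine_panel()].
#' @param groups group labels to build networks for (default
#'   `c("HIV", "HIV_AS")`).
#' @param n_top_genes keep only the `n_top_genes` most variable genes
#'   (default 500) to stay desk-scale.
#' @param score_min,p_max,n_components,keep_fraction,n_perm,seed passed
#'   through to the association and merge steps.
#' @return Named list of `assoc_network` objects.
#' @export
build_group_networks <- function(mrna, mirna, panel,
                                 groups = c("HIV", "HIV_AS"),
                                 n_top_genes = 500, score_min = 0.4,
                                 p_max = 0.05, n_components = 2,
                                 keep_fraction = 0.1, n_perm = 200,
                                 seed = 1) {
  stopifnot(inherits(mrna, "expression_matrix"),
            inherits(mirna, "expression_matrix"),
            inherits(panel, "cytokine_panel"))
  used <- intersect(samples_in_groups(mrna, groups),
                    intersect(colnames(mirna$values),
                              rownames(panel$values)))
  vars <- apply(mrna$values[, used, drop = FALSE], 1, stats::var)
  top <- rownames(mrna$values)[order(-vars)][
    seq_len(min(n_top_genes, nrow(mrna$values)))]
  kinds <- c(stats::setNames(rep("gene", length(top)), top),
             stats::setNames(rep("mirna", nrow(mirna$values)),
                             rownames(mirna$values)),
             stats::setNames(rep("cytokine", ncol(panel$values)),
                             colnames(panel$values)))
  nets <- list()
  for (g in groups) {
    samp <- intersect(samples_in_groups(mrna, g),
                      intersect(colnames(mirna$values),
                                rownames(panel$values)))
    ga <- t(mrna$values[top, samp, drop = FALSE])
    mi <- t(mirna$values[, samp, drop = FALSE])
    # cytokines enter on the log scale, comparable to the log-scale
    # expression blocks
    cy <- log2(panel$values[samp, , drop = FALSE])
    edges <- list(
      pairwise_spls_associations(ga, mi, n_components, keep_fraction,
                                 n_perm, seed = seed),
      pairwise_spls_associations(ga, cy, n_components, keep_fraction,
                                 n_perm, seed = seed + 1),
      pairwise_spls_associations(mi, cy, n_components, keep_fraction,
                                 n_perm, seed = seed + 2))
    nets[[g]] <- merge_networks(edges, kinds, score_min = score_min,
                                p_max = p_max)
  }
  nets
}

#' Write an association network to GraphML
#'
#' Node attributes: kind, community (when present), and any centrality
#' columns supplied via `centrality`.
#'
#' @param net an `assoc_network`.
#' @param path output file.
#' @param centrality optional `data.frame` from
#'   [differential_centrality()].
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, centrality = NULL) {
  g <- as_igraph(net)
  if (!is.null(net$communities))
    igraph::V(g)$community <- unname(net$communities[igraph::V(g)$name])
  if (!is.null(centrality)) {
    idx <- match(igraph::V(g)$name, centrality$node)
    for (col in setdiff(colnames(centrality), c("node", "kind")))
      g <- igraph::set_vertex_attr(g, col, value = centrality[[col]][idx])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
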