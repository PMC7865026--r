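# Shared fixture builders: small deterministic matrices and panels built
# in code. Heavier cohort fixtures come from simulate_cohort() directly.

toy_counts <- function(values, features = NULL, samples = NULL,
                       groups = NULL) {
  m <- matrix(values, nrow = if (is.null(features)) 3 else length(features),
              byrow = TRUE)
  rownames(m) <- features %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  expression_matrix(m, groups %||% rep("CTRL", ncol(m)), kind = "counts")
}

toy_normalized <- function(m, groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_matrix(m, groups %||% rep("HIV", ncol(m)), kind = "normalized")
}

toy_panel <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("cyt", seq_len(ncol(m)))
  cytokine_panel(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force BH: padj_i = min over thresholds t in the
# observed p-values with t >= p_i of n * t / #{p <= t}, capped at 1.
bh_brute <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi - 1e-15]
    min(1, min(vapply(ts, function(t) n * t / sum(p <= t + 1e-15),
                      numeric(1))))
  }, numeric(1))
}

# Closed-form Pearson r and two-sided t-test p, written out longhand.
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * (1 - stats::pt(abs(tt), n - 2)))
}

# spTFscore oracle: prcomp route, formula evaluated term by term with
# explicit loops.
sptf_brute <- function(x, cum_var = 0.5) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > ev[1] * 1e-10
  v <- ev[keep] / sum(ev[keep])
  m <- which(cumsum(v) >= cum_var - 1e-12)[1]
  scores <- numeric(nrow(x))
  if (m >= 2) {
    for (j in seq_len(nrow(x))) {
      acc <- 0
      for (i in 2:m) acc <- acc + pc$x[j, i]^2 * v[i]
      scores[j] <- sqrt(acc)
    }
  }
  weights <- numeric(ncol(x))
  if (m >= 2) {
    for (g in seq_len(ncol(x))) {
      acc <- 0
      for (i in 2:m) acc <- acc + pc$rotation[g, i]^2 * v[i]
      weights[g] <- sqrt(acc) / (1 - v[1])
    }
  }
  list(scores = scores, weights = weights, m = m, v = v)
}

# Power-iteration eigenvector centrality oracle on |weights|, per
# connected component, scaled by the component's spectral radius and
# globally max-normalized.
centrality_brute <- function(net, node_universe = NULL) {
  ids <- node_universe %||% net$nodes$id
  cent <- stats::setNames(rep(0, length(ids)), ids)
  if (!nrow(net$edges)) return(cent)
  nodes <- sort(unique(c(net$edges$u, net$edges$v)))
  a <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(net$edges))) {
    w <- abs(net$edges$weight[k])
    a[net$edges$u[k], net$edges$v[k]] <- w
    a[net$edges$v[k], net$edges$u[k]] <- w
  }
  # connected components by BFS
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, nodes[a[v, ] > 0 & is.na(comp)])
    }
  }
  for (k in seq_len(cid)) {
    members <- nodes[comp == k]
    if (length(members) < 2) next
    sub <- a[members, members, drop = FALSE]
    # shifted power iteration: A + cI has the same Perron vector but a
    # strictly dominant eigenvalue (plain iteration oscillates on
    # bipartite components, whose spectrum is symmetric)
    shift <- max(rowSums(sub))
    x <- rep(1, length(members))
    for (it in 1:100000) {
      x_new <- drop(sub %*% x) + shift * x
      x_new <- x_new / sqrt(sum(x_new^2))
      if (max(abs(x_new - x)) < 1e-13) { x <- x_new; break }
      x <- x_new
    }
    lambda <- drop(crossprod(x, sub %*% x)) / sum(x^2)
    x <- abs(x)
    cent[members] <- x / max(x) * lambda
  }
  if (max(cent) > 0) cent <- cent / max(cent)
  cent
}

# deterministic per-iteration seeds below 2^31
seed_stream <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2, n)
}
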