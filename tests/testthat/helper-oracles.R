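# Brute-force oracles, kept deliberately naive and independent of the
# package's computation paths.

toy_profile <- function(mat, ids = NULL, samples = NULL) {
  if (is.null(ids)) ids <- sprintf("t%02d", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(ids, samples)
  as_profile(mat)
}

# Kendall tau-b by exhaustive pair enumeration
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1
      if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(sapply(split(seq_len(n), x), function(g) length(g) * (length(g) - 1) / 2))
  n2 <- sum(sapply(split(seq_len(n), y), function(g) length(g) * (length(g) - 1) / 2))
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

# mid-rank Spearman through explicit rank construction and the raw
# product-moment formula
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) return(NA_real_)
  num / den
}

# all-pairs shortest paths on a small undirected graph, by breadth-first
# search from every node
oracle_shortest_paths <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    adj[edges$a[k], edges$b[k]] <- TRUE
    adj[edges$b[k], edges$a[k]] <- TRUE
  }
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(dist) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ])) {
          if (dist[s, w] > d) { dist[s, w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  dist
}

# NetworkAnalyzer-convention metrics for graphs small enough to enumerate
oracle_metrics <- function(nodes, edges) {
  n <- length(nodes)
  deg <- setNames(numeric(n), nodes)
  for (k in seq_len(nrow(edges))) {
    deg[edges$a[k]] <- deg[edges$a[k]] + 1
    deg[edges$b[k]] <- deg[edges$b[k]] + 1
  }
  E <- nrow(edges)
  dist <- oracle_shortest_paths(nodes, edges)
  finite <- dist[upper.tri(dist)][is.finite(dist[upper.tri(dist)])]
  finite <- finite[finite > 0]
  # local clustering, nodes of degree < 2 contribute 0
  has_edge <- function(u, v) {
    any((edges$a == u & edges$b == v) | (edges$a == v & edges$b == u))
  }
  cc <- sapply(nodes, function(v) {
    nb <- unique(c(edges$b[edges$a == v], edges$a[edges$b == v]))
    if (length(nb) < 2) return(0)
    cnt <- 0
    pairs <- utils::combn(nb, 2)
    for (q in seq_len(ncol(pairs))) if (has_edge(pairs[1, q], pairs[2, q])) cnt <- cnt + 1
    cnt / choose(length(nb), 2)
  })
  # components by flood fill
  comp <- setNames(rep(NA_integer_, n), nodes); cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    comp[is.finite(dist[s, ])] <- cid
  }
  sizes <- table(comp)
  bigc <- names(sizes)[which.max(sizes)]
  bignodes <- which(comp == as.integer(bigc))
  bigdist <- dist[bignodes, bignodes, drop = FALSE]
  ecc <- apply(bigdist, 1, max)
  density <- if (n > 1) 2 * E / (n * (n - 1)) else NA_real_
  list(
    n_nodes = n, n_edges = E,
    avg_neighbors = 2 * E / n,
    density = density,
    heterogeneity = sqrt(mean(deg^2) - mean(deg)^2) / mean(deg),
    centralization = if (n > 2) (n / (n - 2)) * (max(deg) / (n - 1) - density) else NA_real_,
    clustering_coefficient = mean(cc),
    characteristic_path_length = mean(finite),
    diameter = if (length(bignodes) > 1) max(ecc) else 0,
    radius = if (length(bignodes) > 1) min(ecc) else 0,
    n_components = cid
  )
}

# random correlation-record tibble for network construction
random_results <- function(n_nodes, p_edge, seed, method = "spearman") {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n_nodes))
    pairs <- t(utils::combn(ids, 2))
    keep <- runif(nrow(pairs)) < p_edge
    tibble::tibble(
      taxon_i = pairs[keep, 1], taxon_j = pairs[keep, 2],
      r = runif(sum(keep), 0.61, 0.99),
      p = rep(1e-6, sum(keep)),
      method = method, policy = 5L
    )
  })
}
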