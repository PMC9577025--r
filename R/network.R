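#' Build a signed association network from pair correlations
#'
#' Thresholds an edge list of pair correlations into an undirected network.
#' An edge is kept iff `p < p_cutoff` and, for a co-occurrence network,
#' `r > r_cutoff`, or for a co-exclusive network, `r < -r_cutoff` — both
#' inequalities strict. Nodes are the endpoints of kept edges.
#'
#' @param results tibble with columns `taxon_i`, `taxon_j`, `r`, `p` (and
#'   optionally `method`, `policy`) from a single method/policy
#'   combination.
#' @param r_cutoff absolute coefficient cutoff (default 0.6).
#' @param p_cutoff p-value cutoff (default 0.001).
#' @param kind `"co_occurrence"` (positive edges) or `"co_exclusive"`
#'   (negative edges).
#' @return An `assoc_network` (an igraph graph with `kind`, `method`,
#'   `policy` and cutoff graph attributes; edges carry `weight` = r and
#'   `sign`).
#' @export
build_network <- function(results, r_cutoff = 0.6, p_cutoff = 0.001,
                          kind = c("co_occurrence", "co_exclusive")) {
  kind <- match.arg(kind)
  if ("method" %in% names(results) && dplyr::n_distinct(results$method) > 1) {
    abort("results mix several correlation methods; build one network per method")
  }
  if ("policy" %in% names(results) && dplyr::n_distinct(results$policy) > 1) {
    abort("results mix several filter policies; build one network per policy")
  }
  keep <- !is.na(results$r) & !is.na(results$p) & results$p < p_cutoff &
    (if (kind == "co_occurrence") results$r > r_cutoff else results$r < -r_cutoff)
  edges <- results[keep, , drop = FALSE]
  g <- if (nrow(edges) == 0) {
    igraph::make_empty_graph(0, directed = FALSE)
  } else {
    igraph::graph_from_data_frame(
      data.frame(
        from = edges$taxon_i, to = edges$taxon_j,
        weight = edges$r,
        sign = ifelse(edges$r > 0, "+", "-"),
        stringsAsFactors = FALSE
      ),
      directed = FALSE
    )
  }
  g <- igraph::set_graph_attr(g, "kind", kind)
  g <- igraph::set_graph_attr(g, "method",
    if ("method" %in% names(results) && nrow(results)) results$method[1] else NA_character_)
  g <- igraph::set_graph_attr(g, "policy",
    if ("policy" %in% names(results) && nrow(results)) results$policy[1] else NA_integer_)
  g <- igraph::set_graph_attr(g, "r_cutoff", r_cutoff)
  g <- igraph::set_graph_attr(g, "p_cutoff", p_cutoff)
  class(g) <- unique(c("assoc_network", class(g)))
  g
}

network_kind <- function(network) {
  igraph::graph_attr(network, "kind") %||% NA_character_
}

# canonical edge keys "a|b|sign" with a < b
edge_keys <- function(network) {
  if (igraph::ecount(network) == 0) return(character(0))
  el <- igraph::as_edgelist(network)
  sg <- igraph::edge_attr(network, "sign") %||% rep("+", nrow(el))
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  paste(a, b, sg, sep = "|")
}

#' Topology metrics of an association network
#'
#' One-row tibble of the standard NetworkAnalyzer-style metrics:
#' `avg_neighbors = 2E/N`, `density = 2E/(N(N-1))`,
#' `heterogeneity = sqrt(var(degree)) / mean(degree)` (population
#' variance), `centralization = N/(N-2) * (max_degree/(N-1) - density)`,
#' mean local clustering (nodes with degree < 2 contribute 0),
#' characteristic path length averaged over connected node pairs, and
#' diameter/radius computed on the largest connected component. All path
#' metrics ignore edge weights. Metrics undefined for very small graphs are
#' reported as `NA` rather than erroring.
#'
#' @param network an `assoc_network` (or any undirected igraph graph).
#' @return One-row tibble (see fields above plus `n_nodes`, `n_edges`,
#'   `n_components`).
#' @export
compute_metrics <- function(network) {
  g <- network
  if (!is.null(igraph::edge_attr(g, "weight"))) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (N == 0) {
    return(tibble::tibble(
      n_nodes = 0L, n_edges = 0L, avg_neighbors = NA_real_,
      diameter = NA_real_, radius = NA_real_,
      characteristic_path_length = NA_real_,
      clustering_coefficient = NA_real_, density = NA_real_,
      heterogeneity = NA_real_, centralization = NA_real_,
      n_components = 0L
    ))
  }
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  density <- if (N > 1) 2 * E / (N * (N - 1)) else NA_real_
  het <- if (mean(deg) > 0) {
    sqrt(mean(deg^2) - mean(deg)^2) / mean(deg)
  } else {
    NA_real_
  }
  centralization <- if (N > 2) {
    (N / (N - 2)) * (max(deg) / (N - 1) - density)
  } else {
    NA_real_
  }
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  clustering <- mean(loc)
  big <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  diam <- if (igraph::vcount(big) > 1) igraph::diameter(big, weights = NA) else 0
  rad <- if (igraph::vcount(big) > 1) igraph::radius(big) else 0
  cpl <- if (E > 0) igraph::mean_distance(g, unconnected = TRUE) else NA_real_
  tibble::tibble(
    n_nodes = N, n_edges = E,
    avg_neighbors = 2 * E / N,
    diameter = as.numeric(diam),
    radius = as.numeric(rad),
    characteristic_path_length = cpl,
    clustering_coefficient = clustering,
    density = density,
    heterogeneity = het,
    centralization = centralization,
    n_components = comp$no
  )
}

#' Hub subnetwork of the most connected nodes
#'
#' Selects the `top_k` highest-degree nodes (degree ties at the boundary
#' broken by lexicographic taxon ID, deterministically, and reported via the
#' `tie_note` attribute) plus all their first neighbours, and returns the
#' induced subgraph.
#'
#' @param network a non-empty `assoc_network`.
#' @param top_k number of hub nodes (default 10).
#' @return `assoc_network` induced on the hubs and their first neighbours.
#' @export
hub_subnetwork <- function(network, top_k = 10) {
  N <- igraph::vcount(network)
  if (N == 0) abort("hub_subnetwork() needs a non-empty network")
  nm <- igraph::V(network)$name %||% as.character(seq_len(N))
  deg <- igraph::degree(network)
  ord <- order(-deg, nm)
  k <- min(top_k, N)
  hubs <- ord[seq_len(k)]
  tie_note <- NULL
  if (k < N && deg[ord[k]] == deg[ord[k + 1]]) {
    tie_note <- sprintf(
      "degree tie at rank %d (degree %d) broken lexicographically", k, deg[ord[k]]
    )
    inform(tie_note)
  }
  nbrs <- unique(unlist(igraph::adjacent_vertices(network, hubs)))
  keep <- sort(unique(c(hubs, nbrs)))
  sub <- igraph::induced_subgraph(network, keep)
  class(sub) <- unique(c("assoc_network", class(sub)))
  attr(sub, "tie_note") <- tie_note
  sub
}

#' Consensus (intersection) of association networks
#'
#' The consensus keeps edges present in every member network (matched by
#' unordered endpoint pair plus sign); its node set is the endpoints of the
#' surviving edges and each consensus edge weight is the mean of the member
#' weights. All members must be of the same kind.
#'
#' @param networks list of `assoc_network` objects of one kind.
#' @return Consensus `assoc_network`.
#' @export
consensus_network <- function(networks) {
  if (!length(networks)) abort("need at least one network")
  kinds <- unique(vapply(networks, network_kind, character(1)))
  if (length(kinds) > 1) {
    abort(sprintf("cannot take a consensus across kinds: %s", paste(kinds, collapse = ", ")))
  }
  keys <- lapply(networks, edge_keys)
  shared <- Reduce(intersect, keys)
  weights <- vapply(shared, function(kk) {
    mean(vapply(seq_along(networks), function(i) {
      w <- igraph::edge_attr(networks[[i]], "weight") %||%
        rep(NA_real_, igraph::ecount(networks[[i]]))
      w[match(kk, keys[[i]])]
    }, double(1)))
  }, double(1))
  parts <- strsplit(shared, "|", fixed = TRUE)
  df <- tibble::tibble(
    taxon_i = vapply(parts, `[`, character(1), 1),
    taxon_j = vapply(parts, `[`, character(1), 2),
    r = unname(weights),
    p = 0
  )
  out <- build_network(df,
    r_cutoff = -Inf, p_cutoff = Inf,
    kind = if (is.na(kinds)) "co_occurrence" else kinds
  )
  # preserve signs exactly as stored
  if (igraph::ecount(out)) {
    igraph::E(out)$sign <- vapply(parts, `[`, character(1), 3)
  }
  out <- igraph::set_graph_attr(out, "kind", kinds)
  out <- igraph::set_graph_attr(out, "method", "consensus")
  class(out) <- unique(c("assoc_network", class(out)))
  out
}

#' Overlap between two networks
#'
#' @param net_a,net_b `assoc_network` objects of the same kind.
#' @return Tibble with `shared_edges` (unordered pair + sign matches) and
#'   `shared_nodes` (bare node-set intersection).
#' @export
overlap_counts <- function(net_a, net_b) {
  if (!identical(network_kind(net_a), network_kind(net_b))) {
    abort("overlap_counts() requires networks of the same kind")
  }
  na <- igraph::V(net_a)$name %||% character(0)
  nb <- igraph::V(net_b)$name %||% character(0)
  tibble::tibble(
    shared_edges = length(intersect(edge_keys(net_a), edge_keys(net_b))),
    shared_nodes = length(intersect(na, nb))
  )
}

#' Export a network for external tools
#'
#' GraphML (loadable by Cytoscape and other graph tools) or a TSV edge list
#' with columns `source`, `target`, `sign`, `weight`.
#'
#' @param network an `assoc_network`.
#' @param path output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- network
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- if (igraph::ecount(network)) igraph::as_edgelist(network) else
      matrix(character(0), 0, 2)
    tb <- tibble::tibble(
      source = el[, 1],
      target = el[, 2],
      sign = igraph::edge_attr(network, "sign") %||% character(0),
      weight = igraph::edge_attr(network, "weight") %||% double(0)
    )
    readr::write_tsv(tb, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a TSV edge list back into a network
#'
#' @param path file written by [export_network(format = "edge_tsv")].
#' @param kind network kind of the stored edges.
#' @return An `assoc_network`.
#' @export
read_network_edges <- function(path, kind = c("co_occurrence", "co_exclusive")) {
  kind <- match.arg(kind)
  tb <- readr::read_tsv(path,
    col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      sign = readr::col_character(), weight = readr::col_double()
    ), progress = FALSE
  )
  build_network(
    tibble::tibble(taxon_i = tb$source, taxon_j = tb$target, r = tb$weight, p = 0),
    r_cutoff = -Inf, p_cutoff = Inf, kind = kind
  )
}

#' @describeIn build_network tidy the network into an edge tibble
#'   (`taxon_i`, `taxon_j`, `sign`, `weight`).
#' @param x an `assoc_network`.
#' @param ... unused.
#' @method tidy assoc_network
#' @export
tidy.assoc_network <- function(x, ...) {
  el <- if (igraph::ecount(x)) igraph::as_edgelist(x) else matrix(character(0), 0, 2)
  out <- tibble::tibble(
    taxon_i = pmin(el[, 1], el[, 2]),
    taxon_j = pmax(el[, 1], el[, 2]),
    sign = igraph::edge_attr(x, "sign") %||% character(0),
    weight = igraph::edge_attr(x, "weight") %||% double(0)
  )
  dplyr::arrange(out, .data$taxon_i, .data$taxon_j)
}

#' @describeIn build_network one-row tibble of topology metrics (same as
#'   [compute_metrics()]).
#' @method glance assoc_network
#' @export
glance.assoc_network <- function(x, ...) compute_metrics(x)

#' @describeIn build_network quick force-directed plot of the network.
#' @param object an `assoc_network`.
#' @method autoplot assoc_network
#' @export
autoplot.assoc_network <- function(object, ...) {
  if (igraph::vcount(object) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
      ggplot2::labs(title = "empty network"))
  }
  g <- object
  class(g) <- "igraph"
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$name)],
    y = nodes$y[match(el[, 1], nodes$name)],
    xend = nodes$x[match(el[, 2], nodes$name)],
    yend = nodes$y[match(el[, 2], nodes$name)],
    sign = igraph::edge_attr(g, "sign") %||% rep("+", nrow(el))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$sign),
      alpha = 0.6
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 1.5) +
    ggplot2::scale_colour_manual(values = c("+" = "#2166ac", "-" = "#b2182b")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "sign")
}
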