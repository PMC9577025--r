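pair_results <- function(...) {
  rows <- list(...)
  tibble::tibble(
    taxon_i = sapply(rows, `[[`, 1),
    taxon_j = sapply(rows, `[[`, 2),
    r = as.numeric(sapply(rows, `[[`, 3)),
    p = as.numeric(sapply(rows, `[[`, 4)),
    method = "spearman", policy = 5L
  )
}

test_that("edges are thresholded strictly by sign, cutoff and p-value", {
  res <- pair_results(
    list("A", "B", 0.7, 1e-4),
    list("A", "C", -0.65, 1e-4),
    list("B", "C", 0.5, 1e-5)
  )
  co <- build_network(res, kind = "co_occurrence")
  ex <- build_network(res, kind = "co_exclusive")
  expect_equal(tidy(co)$taxon_i, "A")
  expect_equal(tidy(co)$taxon_j, "B")
  expect_equal(tidy(ex)$taxon_j, "C")
  expect_equal(tidy(ex)$sign, "-")

  # boundary: r = 0.6 exactly and p = 0.001 exactly are both excluded
  bound <- pair_results(list("A", "B", 0.6, 1e-9), list("A", "C", 0.9, 0.001))
  expect_equal(igraph::ecount(build_network(bound, kind = "co_occurrence")), 0)
  expect_equal(igraph::vcount(build_network(res[0, ], kind = "co_occurrence")), 0)

  mixed <- res
  mixed$method <- c("spearman", "pearson", "spearman")
  expect_error(build_network(mixed, kind = "co_occurrence"), "mix")
})

test_that("edge counts are monotone in both cutoffs", {
  res <- random_results(15, 0.6, seed = 31)
  res$r <- res$r * sample(c(1, -1), nrow(res), replace = TRUE)
  res$p <- runif(nrow(res), 0, 0.01)
  ec <- function(rc, pc) igraph::ecount(build_network(res, rc, pc, "co_occurrence"))
  for (rc in c(0.6, 0.7, 0.8, 0.9)) expect_gte(ec(rc, 0.001), ec(rc + 0.05, 0.001))
  for (pc in c(0.01, 0.005, 0.001)) expect_gte(ec(0.6, pc), ec(0.6, pc / 2))
})

test_that("topology metrics match closed forms on canonical graphs", {
  k3 <- build_network(pair_results(
    list("A", "B", 0.9, 1e-6), list("B", "C", 0.9, 1e-6), list("A", "C", 0.9, 1e-6)
  ), kind = "co_occurrence")
  mk3 <- compute_metrics(k3)
  expect_equal(mk3$density, 1)
  expect_equal(mk3$clustering_coefficient, 1)
  expect_equal(mk3$diameter, 1)
  expect_equal(mk3$n_components, 1L)
  expect_equal(mk3$heterogeneity, 0) # 2-regular

  path <- build_network(pair_results(
    list("A", "B", 0.9, 1e-6), list("B", "C", 0.9, 1e-6)
  ), kind = "co_occurrence")
  mp <- compute_metrics(path)
  expect_equal(mp$characteristic_path_length, 4 / 3)
  expect_equal(mp$diameter, 2)
  expect_equal(mp$radius, 1)

  # degenerate graphs return defined values or NA markers, never crash
  empty <- build_network(pair_results(list("A", "B", 0.1, 0.5)), kind = "co_occurrence")
  me <- compute_metrics(empty)
  expect_equal(me$n_nodes, 0L)
  single <- build_network(pair_results(list("A", "B", 0.9, 1e-6)), kind = "co_occurrence")
  ms <- compute_metrics(single)
  expect_equal(ms$n_edges, 1L)
  expect_true(is.na(ms$centralization))
})

test_that("topology metrics agree with a brute-force oracle on small graphs", {
  for (seed in c(101, 202, 303, 404)) {
    res <- random_results(8, 0.45, seed = seed)
    net <- build_network(res, kind = "co_occurrence")
    if (igraph::ecount(net) == 0) next
    ed <- tidy(net)
    nodes <- sort(unique(c(ed$taxon_i, ed$taxon_j)))
    oracle <- oracle_metrics(nodes, data.frame(a = ed$taxon_i, b = ed$taxon_j))
    got <- compute_metrics(net)
    for (f in c(
      "n_nodes", "n_edges", "avg_neighbors", "density", "heterogeneity",
      "centralization", "clustering_coefficient", "characteristic_path_length",
      "diameter", "radius", "n_components"
    )) {
      expect_equal(got[[f]], oracle[[f]], tolerance = 1e-12, label = f,
        ignore_attr = TRUE)
    }
  }
})

test_that("hub subnetworks take top-degree nodes plus first neighbours", {
  star <- build_network(pair_results(
    list("hub", "a", 0.9, 1e-6), list("hub", "b", 0.9, 1e-6),
    list("hub", "c", 0.9, 1e-6)
  ), kind = "co_occurrence")
  sub <- hub_subnetwork(star, top_k = 1)
  expect_equal(igraph::vcount(sub), 4)

  two_tri <- build_network(pair_results(
    list("a1", "a2", 0.9, 1e-6), list("a2", "a3", 0.9, 1e-6), list("a1", "a3", 0.9, 1e-6),
    list("b1", "b2", 0.9, 1e-6), list("b2", "b3", 0.9, 1e-6), list("b1", "b3", 0.9, 1e-6)
  ), kind = "co_occurrence")
  tri <- suppressMessages(hub_subnetwork(two_tri, top_k = 1))
  expect_equal(sort(igraph::V(tri)$name), c("a1", "a2", "a3")) # lexicographic tie

  # induced node set equals the brute-force union of closed neighbourhoods
  res <- random_results(12, 0.4, seed = 77)
  net <- build_network(res, kind = "co_occurrence")
  sub <- suppressMessages(hub_subnetwork(net, top_k = 3))
  ed <- tidy(net)
  deg <- table(c(ed$taxon_i, ed$taxon_j))
  ord <- names(deg)[order(-deg, names(deg))]
  hubs <- ord[1:3]
  expected <- sort(unique(c(hubs, unlist(lapply(hubs, function(h) {
    c(ed$taxon_j[ed$taxon_i == h], ed$taxon_i[ed$taxon_j == h])
  })))))
  expect_equal(sort(igraph::V(sub)$name), expected)
})

test_that("consensus networks are intersections with averaged weights", {
  net <- build_network(random_results(10, 0.5, seed = 8), kind = "co_occurrence")
  self <- consensus_network(list(net, net))
  expect_setequal(tidy(self)$taxon_i, tidy(net)$taxon_i)
  expect_equal(igraph::ecount(self), igraph::ecount(net))

  a <- build_network(pair_results(list("A", "B", 0.7, 1e-6)), kind = "co_occurrence")
  b <- build_network(pair_results(list("C", "D", 0.7, 1e-6)), kind = "co_occurrence")
  expect_equal(igraph::ecount(consensus_network(list(a, b))), 0)

  n1 <- build_network(random_results(10, 0.6, seed = 1), kind = "co_occurrence")
  n2 <- build_network(random_results(10, 0.6, seed = 2), kind = "co_occurrence")
  n3 <- build_network(random_results(10, 0.6, seed = 3), kind = "co_occurrence")
  cons <- consensus_network(list(n1, n2, n3))
  brute <- Reduce(intersect, lapply(list(n1, n2, n3), function(g) {
    ed <- tidy(g)
    paste(ed$taxon_i, ed$taxon_j)
  }))
  expect_setequal(paste(tidy(cons)$taxon_i, tidy(cons)$taxon_j), brute)
  # consensus edge set is a subset of every member's, order-invariantly
  cons2 <- consensus_network(list(n3, n1, n2))
  expect_equal(dplyr::arrange(tidy(cons2), taxon_i, taxon_j), tidy(cons))
  for (g in list(n1, n2, n3)) {
    expect_true(all(paste(tidy(cons)$taxon_i, tidy(cons)$taxon_j) %in%
      paste(tidy(g)$taxon_i, tidy(g)$taxon_j)))
  }
  # averaged weights
  if (igraph::ecount(cons) > 0) {
    key <- paste(tidy(cons)$taxon_i, tidy(cons)$taxon_j)[1]
    ws <- sapply(list(n1, n2, n3), function(g) {
      ed <- tidy(g)
      ed$weight[paste(ed$taxon_i, ed$taxon_j) == key]
    })
    expect_equal(tidy(cons)$weight[1], mean(ws))
  }

  ex <- build_network(pair_results(list("A", "B", -0.7, 1e-6)), kind = "co_exclusive")
  expect_error(consensus_network(list(a, ex)), "kind")
})

test_that("overlap counts enumerate shared edges and nodes", {
  n1 <- build_network(random_results(10, 0.5, seed = 4), kind = "co_occurrence")
  ov_self <- overlap_counts(n1, n1)
  expect_equal(ov_self$shared_edges, igraph::ecount(n1))
  expect_equal(ov_self$shared_nodes, igraph::vcount(n1))

  a <- build_network(pair_results(
    list("A", "B", 0.7, 1e-6), list("B", "C", 0.7, 1e-6), list("C", "D", 0.7, 1e-6)
  ), kind = "co_occurrence")
  b <- build_network(pair_results(
    list("A", "B", 0.8, 1e-6), list("B", "C", 0.8, 1e-6), list("E", "F", 0.8, 1e-6)
  ), kind = "co_occurrence")
  ov <- overlap_counts(a, b)
  expect_equal(ov$shared_edges, 2L)
  expect_equal(ov$shared_nodes, 3L)

  d <- build_network(pair_results(list("X", "Y", 0.9, 1e-6)), kind = "co_occurrence")
  expect_equal(unlist(overlap_counts(a, d)), c(shared_edges = 0L, shared_nodes = 0L))
})

test_that("networks export and re-import losslessly", {
  net <- build_network(random_results(8, 0.6, seed = 12), kind = "co_occurrence")
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f, format = "edge_tsv")
  back <- read_network_edges(f, kind = "co_occurrence")
  expect_equal(tidy(back), tidy(net))

  g <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, g, format = "graphml")
  reread <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(reread), igraph::ecount(net))

  empty <- build_network(random_results(8, 0.6, seed = 12)[0, ], kind = "co_occurrence")
  ge <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, ge, format = "graphml")
  expect_equal(igraph::vcount(igraph::read_graph(ge, format = "graphml")), 0)

  k3 <- build_network(pair_results(
    list("A", "B", 0.9, 1e-6), list("B", "C", 0.9, 1e-6), list("A", "C", 0.9, 1e-6)
  ), kind = "co_occurrence")
  fk <- withr::local_tempfile(fileext = ".tsv")
  export_network(k3, fk, format = "edge_tsv")
  tk <- readr::read_tsv(fk, show_col_types = FALSE)
  expect_equal(nrow(tk), 3L)
  expect_equal(length(unique(c(tk$source, tk$target))), 3L)
})
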