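make_edges <- function(df) {
  df$distance_yx <- df$distance
  class(df) <- c("association_edges", "data.frame")
  df
}

test_that("tree growth follows shortest-path semantics", {
  edges <- make_edges(data.frame(
    code_x = c("R", "R", "A"), code_y = c("A", "B", "B"),
    distance = c(1.0, 3.0, 1.5), stringsAsFactors = FALSE))
  tr <- build_tree("R", edges)
  expect_identical(attr(tr, "root"), "R")
  expect_equal(tr$cumulative_distance[tr$code == "B"], 2.5)
  expect_equal(tr$depth[tr$code == "B"], 2L)
  expect_identical(tr$parent[tr$code == "B"], "A")
  expect_equal(tr$depth[tr$code == "R"], 0L)
  expect_equal(tr$cumulative_distance[tr$code == "R"], 0)
  expect_true(is.na(tr$parent[tr$code == "R"]))
})

test_that("single edge and edge-local attachment behave", {
  edges <- make_edges(data.frame(code_x = "R", code_y = "A",
                                 distance = 2.0, stringsAsFactors = FALSE))
  tr <- build_tree("R", edges)
  expect_equal(tr$cumulative_distance[tr$code == "A"], 2.0)
  expect_equal(tr$depth[tr$code == "A"], 1L)

  # nearest-neighbour attachment can differ from shortest paths:
  # R-A 1.0, R-B 1.8, A-B 1.0 -> greedy attaches B under A (edge 1.0)
  # even though the R-B path is shorter (1.8 < 2.0)
  edges2 <- make_edges(data.frame(
    code_x = c("R", "R", "A"), code_y = c("A", "B", "B"),
    distance = c(1.0, 1.8, 1.0), stringsAsFactors = FALSE))
  greedy <- build_tree("R", edges2, method = "edge")
  expect_identical(greedy$parent[greedy$code == "B"], "A")
  expect_equal(greedy$cumulative_distance[greedy$code == "B"], 2.0)
  dij <- build_tree("R", edges2)
  expect_identical(dij$parent[dij$code == "B"], "R")
})

test_that("unreachable codes are absent and ties break lexicographically", {
  edges <- make_edges(data.frame(
    code_x = c("R", "R", "X"), code_y = c("A", "B", "Y"),
    distance = c(1, 1, 1), stringsAsFactors = FALSE))
  tr <- build_tree("R", edges)
  expect_setequal(tr$code, c("R", "A", "B"))
  # equal-distance nodes appear in lexicographic order
  expect_identical(tr$code, c("R", "A", "B"))
})

test_that("tree distances match the igraph shortest-path oracle", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (i in seq_len(100)) {
    n <- sample(5:50, 1L)
    edges <- random_edge_graph(n, sample(n:(3L * n), 1L))
    root <- edges$code_x[1L]
    tr <- build_tree(root, edges)
    want <- igraph_distances_from(edges, root)
    got <- stats::setNames(tr$cumulative_distance, tr$code)
    reach <- names(want)[is.finite(want)]
    expect_setequal(tr$code, reach)
    expect_equal(got[reach], want[reach], tolerance = 1e-9)
    # parent links are consistent: depth and cumulative recurrences
    for (j in seq_len(nrow(tr))) {
      p <- tr$parent[j]
      if (is.na(p)) next
      prow <- tr[tr$code == p, ]
      expect_equal(tr$depth[j], prow$depth + 1L)
      expect_gte(tr$cumulative_distance[j],
                 prow$cumulative_distance - 1e-12)
    }
  }
})

test_that("asymmetric conditional edges use the away-from-root direction", {
  edges <- data.frame(code_x = "A", code_y = "R",
                      distance = 5, distance_yx = 1,
                      stringsAsFactors = FALSE)
  class(edges) <- c("association_edges", "data.frame")
  tr <- build_tree("R", edges)
  # traversing R -> A must use distance_yx (direction y=R to x=A)
  expect_equal(tr$cumulative_distance[tr$code == "A"], 1)
})

test_that("excluding the direct edge bounds the indirect distance", {
  edges <- make_edges(data.frame(
    code_x = c("R", "R", "A"), code_y = c("B", "A", "B"),
    distance = c(2.0, 1.0, 1.5), stringsAsFactors = FALSE))
  expect_equal(indirect_distance_excluding_direct("R", "B", edges), 2.5)
  only <- make_edges(data.frame(code_x = "R", code_y = "B",
                                distance = 2, stringsAsFactors = FALSE))
  expect_identical(indirect_distance_excluding_direct("R", "B", only), Inf)
  # no direct edge: exclusion is a no-op
  chain <- make_edges(data.frame(
    code_x = c("R", "A"), code_y = c("A", "B"),
    distance = c(1, 1), stringsAsFactors = FALSE))
  expect_equal(indirect_distance_excluding_direct("R", "B", chain), 2)
  expect_error(indirect_distance_excluding_direct("R", "R", chain),
               "differ")
})

test_that("exclusion never beats the unrestricted shortest path", {
  set.seed(32)
  for (i in seq_len(40)) {
    edges <- random_edge_graph(12L, 20L)
    root <- edges$code_x[1L]
    tr <- build_tree(root, edges)
    for (code in setdiff(tr$code, root)) {
      expect_gte(indirect_distance_excluding_direct(root, code, edges),
                 tr$cumulative_distance[tr$code == code] - 1e-12)
    }
  }
})

test_that("exp(-cumulative) multiplies per-edge coefficients along paths", {
  set.seed(33)
  edges <- random_edge_graph(15L, 30L)
  root <- edges$code_x[1L]
  tr <- build_tree(root, edges)
  w <- function(a, b) {
    sel <- (edges$code_x == a & edges$code_y == b) |
      (edges$code_x == b & edges$code_y == a)
    min(edges$distance[sel])
  }
  for (j in which(!is.na(tr$parent))) {
    prod_coeff <- 1
    node <- tr$code[j]
    while (node != root) {
      par <- tr$parent[tr$code == node]
      prod_coeff <- prod_coeff * exp(-w(par, node))
      node <- par
    }
    expect_equal(exp(-tr$cumulative_distance[j]), prod_coeff,
                 tolerance = 1e-9)
  }
})

test_that("candidate ranking uses the shorter distance and filters kinds", {
  edges <- make_edges(data.frame(
    code_x = c("H00001", "H00001", "K00001", "K00001", "H00001"),
    code_y = c("K00001", "D00002", "D00001", "D00002", "C00001"),
    distance = c(1.0, 2.318, 1.9, 1.2, 0.8),
    stringsAsFactors = FALSE))
  dict <- data.frame(
    code = c("H00001", "K00001", "D00001", "D00002", "C00001"),
    kind = c("H", "K", "D", "D", "C"),
    term = c("dis", "prot", "drugA", "drugB", "metab"),
    stems = c("Dis", "Prot", "DrugA", "DrugB", "Metab"),
    stringsAsFactors = FALSE)
  class(dict) <- c("term_dictionary", "data.frame")
  tr <- build_tree("H00001", edges)
  cand <- rank_candidates(tr, edges, dict)
  expect_identical(cand$code, c("D00002", "D00001"))
  # D00002: direct 2.318, indirect via K 2.2 -> ranks by 2.2
  expect_equal(cand$rank_key[cand$code == "D00002"], 2.2)
  expect_equal(cand$direct_distance[cand$code == "D00002"], 2.318)
  # D00001 has no direct edge
  expect_true(is.na(cand$direct_distance[cand$code == "D00001"]))
  expect_equal(cand$indirect_distance[cand$code == "D00001"], 2.9)
  expect_equal(cand$indirect_depth[cand$code == "D00001"], 2L)
  # kinds filter
  all_kinds <- rank_candidates(tr, edges, dict, kinds = c("D", "C"))
  expect_true("C00001" %in% all_kinds$code)
})

test_that("depth histogram sums to the reachable node count", {
  set.seed(34)
  edges <- random_edge_graph(20L, 35L)
  tr <- build_tree(edges$code_x[1L], edges)
  h <- depth_histogram(tr)
  expect_equal(sum(h), nrow(tr))
  expect_equal(unname(h[["0"]]), 1L)
})

test_that("trees round-trip through TSV and Newick", {
  edges <- make_edges(data.frame(
    code_x = c("R", "R", "A", "A"), code_y = c("A", "B", "C", "D"),
    distance = c(1.25, 2.5, 0.75, 1.0), stringsAsFactors = FALSE))
  tr <- build_tree("R", edges)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tree_tsv(tr, tsv)
  back <- read_tree_tsv(tsv)
  expect_identical(attr(back, "root"), "R")
  expect_equal(as.data.frame(back), as.data.frame(tr), ignore_attr = TRUE)

  skip_if_not_installed("ape")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, nwk)
  ph <- ape::read.tree(nwk)
  labs <- c(ph$tip.label, ph$node.label)
  # root-to-node path lengths in the reparsed tree match cumulative
  depths <- ape::node.depth.edgelength(ph)
  for (i in seq_len(nrow(tr))) {
    expect_equal(depths[match(tr$code[i], labs)],
                 tr$cumulative_distance[i], tolerance = 1e-9,
                 label = tr$code[i])
  }
})
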