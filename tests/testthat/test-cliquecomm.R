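named_graph <- function(edges, n = NULL, prefix = "n") {
  # edges: 2-column matrix of integer endpoints
  nn <- if (is.null(n)) max(edges) else n
  g <- igraph::make_empty_graph(nn, directed = FALSE)
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(nn))
  if (length(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

test_that("k-clique enumeration covers the textbook cases", {
  tri <- named_graph(cbind(c(1, 2, 1), c(2, 3, 3)))
  expect_identical(enumerate_k_cliques(tri, 3), list(c("n01", "n02", "n03")))
  path <- named_graph(cbind(c(1, 2), c(2, 3)))
  expect_identical(enumerate_k_cliques(path, 3), list())
  # k larger than the vertex count -> empty
  expect_identical(enumerate_k_cliques(tri, 5), list())
  expect_error(enumerate_k_cliques(tri, 1), "k must be")
})

test_that("k-clique enumeration equals the brute-force combinations oracle", {
  set.seed(2024)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(12, 0.3)
    igraph::V(g)$name <- sprintf("n%02d", 1:12)
    mine <- enumerate_k_cliques(g, 3)
    oracle <- Filter(function(s) {
      prs <- utils::combn(s, 2)
      all(apply(prs, 2, function(p) igraph::are_adjacent(g, p[1], p[2])))
    }, utils::combn(sort(igraph::V(g)$name), 3, simplify = FALSE))
    oracle <- oracle[order(vapply(oracle, paste, "", collapse = "\r"))]
    expect_identical(mine, oracle)
  }
})

test_that("clique percolation merges triangles sharing an edge, not a vertex", {
  # two triangles sharing edge 2-3 -> one community of 4
  shared_edge <- named_graph(cbind(c(1, 1, 2, 2, 3), c(2, 3, 3, 4, 4)))
  cs <- clique_percolation(shared_edge, 3)
  expect_equal(length(cs$communities), 1)
  expect_identical(cs$communities[[1]], sprintf("n%02d", 1:4))
  # two triangles sharing only vertex 3 -> two communities
  shared_vertex <- named_graph(cbind(c(1, 1, 2, 3, 3, 4),
                                     c(2, 3, 3, 4, 5, 5)))
  cs2 <- clique_percolation(shared_vertex, 3)
  expect_equal(length(cs2$communities), 2)
  # K4: all four triangles pairwise share two nodes -> one community
  k4 <- named_graph(t(utils::combn(4, 2)))
  cs3 <- clique_percolation(k4, 3)
  expect_equal(length(cs3$communities), 1)
  expect_identical(cs3$communities[[1]], sprintf("n%02d", 1:4))
  # graph with no triangle -> no communities
  expect_equal(length(clique_percolation(named_graph(cbind(1, 2), n = 3),
                                         3)$communities), 0)
})

test_that("clique percolation equals the brute-force CPM oracle on random graphs", {
  set.seed(4711)
  for (rep in 1:40) {
    n <- sample(6:18, 1)
    p <- sample(c(0.2, 0.35, 0.5), 1)
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    expect_identical(clique_percolation(g, 3)$communities, cpm_oracle(g, 3))
  }
  # and for k = 4 on a few denser graphs
  for (rep in 1:5) {
    g <- igraph::sample_gnp(10, 0.55)
    igraph::V(g)$name <- sprintf("n%02d", 1:10)
    expect_identical(clique_percolation(g, 4)$communities, cpm_oracle(g, 4))
  }
})

test_that("communities are isomorphism-invariant under relabeling", {
  set.seed(9)
  g <- igraph::sample_gnp(12, 0.35)
  igraph::V(g)$name <- sprintf("n%02d", 1:12)
  perm <- sample(12)
  g2 <- g
  igraph::V(g2)$name <- sprintf("n%02d", perm)
  relabel <- function(comms) {
    mapped <- lapply(comms, function(cm) {
      sort(sprintf("n%02d", perm[match(cm, sprintf("n%02d", 1:12))]))
    })
    mapped[order(vapply(mapped, paste, "", collapse = "\r"))]
  }
  expect_identical(clique_percolation(g2, 3)$communities,
                   relabel(clique_percolation(g, 3)$communities))
})

test_that("adding an edge never separates nodes that shared a community", {
  set.seed(33)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(10, 0.35)
    igraph::V(g)$name <- sprintf("n%02d", 1:10)
    cs <- clique_percolation(g, 3)
    non_edges <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                         upper.tri(matrix(TRUE, 10, 10)), arr.ind = TRUE)
    if (!nrow(non_edges)) next
    pick <- non_edges[sample(nrow(non_edges), 1), ]
    g2 <- igraph::add_edges(g, c(pick[1], pick[2]))
    cs2 <- clique_percolation(g2, 3)
    for (cm in cs$communities) {
      prs <- utils::combn(cm, 2)
      for (j in seq_len(ncol(prs))) {
        expect_equal(same_community(cs2, prs[1, j], prs[2, j]), 1L)
      }
    }
  }
})

test_that("for k = 3 every community is connected and every member is in a triangle", {
  set.seed(101)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(14, 0.3)
    igraph::V(g)$name <- sprintf("n%02d", 1:14)
    cs <- clique_percolation(g, 3)
    tri <- enumerate_k_cliques(g, 3)
    for (cm in cs$communities) {
      sub <- igraph::induced_subgraph(g, cm)
      expect_true(igraph::is_connected(sub))
      in_tri_within <- vapply(cm, function(v) {
        any(vapply(tri, function(t) v %in% t && all(t %in% cm), TRUE))
      }, TRUE)
      expect_true(all(in_tri_within))
    }
  }
})

test_that("same_community implements the symmetric pair indicator", {
  # community carrying the lysozyme core sites 94, 98, 152, 156: a complete
  # graph on the four residues percolates into a single community
  keys <- residue_key("A", c(94, 98, 152, 156))
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- sort(keys)
  g <- igraph::add_edges(g, as.vector(utils::combn(4, 2)))
  cs <- clique_percolation(g, 3)
  a98 <- residue_key("A", 98); a152 <- residue_key("A", 152)
  expect_equal(same_community(cs, a98, a152), 1L)
  expect_equal(same_community(cs, a152, a98), 1L)
  expect_equal(same_community(cs, a98, a98), 1L)   # reflexive containment
  expect_equal(same_community(cs, a98, residue_key("A", 1)), 0L)  # unknown
  # nodes in disjoint communities score 0
  g2 <- named_graph(cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6)))
  cs2 <- clique_percolation(g2, 3)
  expect_equal(length(cs2$communities), 2)
  expect_equal(same_community(cs2, "n01", "n04"), 0L)
})

test_that("community writers emit valid JSON and TSV", {
  g <- named_graph(cbind(c(1, 1, 2, 2, 3), c(2, 3, 3, 4, 4)))
  cs <- clique_percolation(g, 3)
  tf <- tempfile(fileext = ".json")
  write_communities(cs, tf, "json")
  parsed <- jsonlite::fromJSON(tf, simplifyVector = FALSE)
  expect_equal(parsed$k, 3)
  expect_equal(length(parsed$communities), 1)
  tf2 <- tempfile(fileext = ".tsv")
  write_communities(cs, tf2, "tsv")
  tab <- utils::read.delim(tf2)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("community_id", "chain", "res") %in% names(tab)))
})
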