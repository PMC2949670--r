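test_that("degree refinement reaches the k-core fixpoint", {
  expect_equal(igraph::gorder(refine(make_star4(), 2)), 0)
  k4 <- make_complete_graph(4)
  expect_equal(igraph::gorder(refine(k4, 3)), 4)
  p3 <- make_path_graph(3)
  expect_equal(igraph::gorder(refine(p3, 1)), 3)
  expect_error(refine(k4, 0), ">= 1")
})

test_that("refinement agrees with an independent k-core computation", {
  set.seed(7)
  for (i in 1:25) {
    g <- rand_gnp(sample(5:15, 1), sample(c(0.2, 0.4, 0.6), 1))
    core <- igraph::coreness(g)
    for (k in 1:4) {
      expect_setequal(igraph::V(refine(g, k))$name, names(core)[core >= k])
    }
  }
})

test_that("separator search returns the lexicographically smallest minimum cut", {
  bow <- make_bowtie()
  res <- find_separator(bow, 2)
  expect_true(res$found)
  expect_identical(res$separator, "X")

  expect_false(find_separator(make_complete_graph(4), 3)$found)

  p3 <- make_path_graph(3)  # v1 - v2 - v3
  res <- find_separator(p3, 2)
  expect_true(res$found)
  expect_identical(res$separator, "v2")

  # two cut vertices (bridge endpoints): the smaller identifier wins
  bk <- make_bridged_k4s()
  expect_identical(find_separator(bk, 2)$separator, "A1")

  expect_error(find_separator(ppi_graph(rbind(c("A", "B"), c("C", "D"))), 2),
               "connected")
})

test_that("separator search agrees with max-flow connectivity and exhaustive cuts", {
  set.seed(11)
  checked <- 0
  for (i in 1:60) {
    g <- rand_gnp(sample(4:9, 1), sample(c(0.3, 0.5, 0.7), 1))
    if (!igraph::is_connected(g)) next
    truth <- brute_min_cut_size(g)
    for (k in 1:4) {
      if (igraph::gorder(g) <= k) next
      res <- find_separator(g, k)
      if (res$found) {
        expect_equal(length(res$separator), truth)
        rest <- igraph::delete_vertices(g, res$separator)
        expect_false(igraph::is_connected(rest))
      } else {
        # no cut below k: either k-connected by enumeration, or complete
        expect_true(is.na(truth) || truth >= k)
        expect_true(verify_kconnected(g, k))
      }
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("fragmentation handles the canonical small cases in both modes", {
  c5 <- make_ring_graph(5)
  expect_equal(member_sets(decompose_kconnected(c5, 2)),
               list(paste0("v", 1:5)))

  bow <- make_bowtie()
  expect_length(decompose_kconnected(bow, 2, mode = "literal"), 0)
  expect_equal(member_sets(decompose_kconnected(bow, 2, mode = "readd")),
               list(c("A", "B", "X"), c("C", "D", "X")))

  expect_error(decompose_kconnected(ppi_graph(rbind(c("A", "B"), c("C", "D"))), 1),
               "connected")
})

test_that("maximal k-connected extraction matches hand-derived decompositions", {
  two_k4 <- ppi_graph(rbind(t(utils::combn(paste0("A", 1:4), 2)),
                            t(utils::combn(paste0("B", 1:4), 2))))
  expect_equal(member_sets(maximal_kconnected(two_k4, 3)),
               list(paste0("A", 1:4), paste0("B", 1:4)))

  bk <- make_bridged_k4s()
  # readd preserves both K4s; literal discards the bridge-endpoint cut
  # vertex A1, truncating one K4 to a triangle
  expect_equal(member_sets(maximal_kconnected(bk, 2, mode = "readd")),
               list(paste0("A", 1:4), paste0("B", 1:4)))
  expect_equal(member_sets(maximal_kconnected(bk, 2, mode = "literal")),
               list(paste0("A", 2:4), paste0("B", 1:4)))

  expect_length(maximal_kconnected(make_complete_graph(4), 5), 0)
})

test_that("brute-force oracle implements the connectivity definition", {
  c5 <- make_ring_graph(5)
  expect_true(verify_kconnected(c5, 2))
  expect_false(verify_kconnected(c5, 3))
  for (n in 3:6) expect_true(verify_kconnected(make_complete_graph(n), n - 1))
  expect_false(verify_kconnected(rand_tree(5), 2))
  expect_false(verify_kconnected(make_path_graph(3), 3))  # |V| = k
  expect_error(verify_kconnected(make_complete_graph(15), 2), "14")
})

test_that("every emitted subgraph is certified k-connected by the oracle", {
  set.seed(23)
  for (i in 1:50) {
    g <- rand_gnp(sample(5:10, 1), sample(c(0.2, 0.4, 0.6), 1))
    for (k in 1:4) {
      for (mode in c("readd", "literal")) {
        for (s in maximal_kconnected(g, k, mode = mode)) {
          expect_true(verify_kconnected(s, k))
        }
      }
    }
  }
})

test_that("readd-mode levels nest; the literal counterexample is preserved", {
  # readd: every level-(k+1) member set lies inside some level-k set
  set.seed(31)
  for (i in 1:25) {
    g <- rand_gnp(sample(6:10, 1), sample(c(0.4, 0.6), 1))
    prev <- NULL
    for (k in 1:4) {
      cur <- member_sets(maximal_kconnected(g, k, mode = "readd"))
      if (!is.null(prev)) {
        for (s in cur) {
          expect_true(any(vapply(prev, function(p) all(s %in% p), logical(1))))
        }
      }
      prev <- cur
    }
  }
  # literal: K5 sharing a vertex with a triangle breaks nesting — the k=2
  # sweep discards the shared cut vertex (emitting K4), but after degree
  # refinement at k=3 the triangle is gone and the full K5 is emitted
  k5t <- make_k5_triangle()
  expect_equal(member_sets(maximal_kconnected(k5t, 2, mode = "literal")),
               list(paste0("v", 2:5)))
  expect_equal(member_sets(maximal_kconnected(k5t, 3, mode = "literal")),
               list(paste0("v", 1:5)))
  # readd keeps the K5 whole already at k = 2
  expect_true(any(vapply(member_sets(maximal_kconnected(k5t, 2, mode = "readd")),
                         identical, logical(1), paste0("v", 1:5))))
})

test_that("the k-sweep terminates below max degree + 1 and respects filters", {
  set.seed(37)
  for (i in 1:15) {
    g <- rand_gnp(sample(6:12, 1), sample(c(0.3, 0.5), 1))
    cl <- cfa(g, cfa_config(min_cluster_size = 2))
    if (nrow(cl) > 0) {
      expect_lte(max(cl$connectivity_level), max(igraph::degree(g)) + 1)
      expect_true(all(cl$size >= 2))
      k1 <- cl$connectivity_level == 1
      expect_true(all(cl$diameter[k1] <= 4))
      expect_true(all(cl$diameter[!k1] <= cl$connectivity_level[!k1]))
      # no duplicate member sets after union
      keys <- vapply(cl$members, paste, "", collapse = "|")
      expect_false(anyDuplicated(keys) > 0)
    }
  }
})

test_that("cfa resolves the canonical fixtures as derived by hand", {
  # K5: one cluster, found at k = 1..4, labeled with its connectivity 4
  k5 <- cfa(make_complete_graph(5))
  expect_equal(nrow(k5), 1)
  expect_equal(k5$connectivity_level, 4L)
  expect_equal(k5$size, 5L)
  expect_equal(k5$density, 1)

  # path on 10: the only candidate (the whole path) has diameter 9 > 4
  expect_equal(nrow(cfa(make_path_graph(10))), 0)

  bk <- make_bridged_k4s()
  readd <- cfa(bk, cfa_config(separator_mode = "readd"))
  expect_equal(readd$members,
               list(c(paste0("A", 1:4), paste0("B", 1:4)),
                    paste0("A", 1:4), paste0("B", 1:4)),
               ignore_attr = TRUE)
  expect_equal(readd$connectivity_level, c(1L, 3L, 3L))

  literal <- cfa(bk, cfa_config(separator_mode = "literal"))
  expect_equal(literal$members,
               list(c(paste0("A", 1:4), paste0("B", 1:4)), paste0("B", 1:4)),
               ignore_attr = TRUE)
})

test_that("the cluster-score filter drops trees and low-score clusters", {
  # triangle with a pendant chain: the 1-connected component is not a tree
  g <- ppi_graph(rbind(c("A", "B"), c("B", "C"), c("C", "A"), c("C", "D")))
  keep <- cfa(g, cfa_config(min_cluster_size = 4))
  expect_equal(nrow(keep), 1)  # score 2*4/3 = 8/3 > 2
  # a pure tree of 5 vertices has score exactly 2 and is filtered
  tree <- make_path_graph(5)
  with_filter <- cfa(tree, cfa_config(use_cluster_score_filter = TRUE))
  expect_equal(nrow(with_filter), 0)
  without <- cfa(tree, cfa_config(use_cluster_score_filter = FALSE))
  expect_equal(nrow(without), 1)
  # at level k every kept cluster scores above k + 1
  set.seed(41)
  for (i in 1:10) {
    g <- rand_gnp(10, 0.5)
    cl <- cfa(g, cfa_config(use_cluster_score_filter = TRUE, min_cluster_size = 2))
    if (nrow(cl) > 0) {
      expect_true(all(cl$cluster_score > cl$connectivity_level + 1))
    }
  }
})

test_that("cfa handles degenerate inputs", {
  expect_equal(nrow(cfa(ppi_graph(NULL, vertices = "solo"))), 0)
  expect_equal(nrow(cfa(make_complete_graph(5), cfa_config(max_k = 2))), 1)
})
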