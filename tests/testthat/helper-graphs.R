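# Graph fixtures built in code; no stored data.

member_sets <- function(graphs) {
  lapply(graphs, function(g) sort(igraph::V(g)$name))
}

# Two triangles sharing the single vertex X.
make_bowtie <- function() {
  ppi_graph(rbind(c("A", "B"), c("A", "X"), c("B", "X"),
                  c("C", "D"), c("C", "X"), c("D", "X")))
}

# Two K4s (A1..A4, B1..B4) joined by the single bridge edge A1-B1.
make_bridged_k4s <- function() {
  ppi_graph(rbind(t(utils::combn(paste0("A", 1:4), 2)),
                  t(utils::combn(paste0("B", 1:4), 2)),
                  c("A1", "B1")))
}

# K5 on v1..v5 sharing vertex v1 with the triangle v1-T1-T2: the smallest
# witness that discarding separators loses a maximal k-connected subgraph.
make_k5_triangle <- function() {
  ppi_graph(rbind(t(utils::combn(paste0("v", 1:5), 2)),
                  c("v1", "T1"), c("v1", "T2"), c("T1", "T2")))
}

# Star: center c with leaves l1..l3.
make_star4 <- function() {
  ppi_graph(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3")))
}

# Erdos-Renyi G(n, p) with named vertices; caller controls the RNG.
rand_gnp <- function(n, p, prefix = "n") {
  v <- sprintf("%s%02d", prefix, seq_len(n))
  pool <- t(utils::combn(v, 2))
  em <- pool[stats::runif(nrow(pool)) < p, , drop = FALSE]
  ppi_graph(em, vertices = v)
}

# Random tree on n vertices: each vertex attaches to a random predecessor.
rand_tree <- function(n, prefix = "t") {
  v <- sprintf("%s%02d", prefix, seq_len(n))
  if (n < 2) return(ppi_graph(NULL, vertices = v))
  em <- cbind(v[-1], vapply(2:n, function(i) v[sample.int(i - 1, 1)], ""))
  ppi_graph(em)
}

# Random layered DAG over n terms with annotation counts; used for the
# informative-term antichain property.
rand_dag <- function(n_terms, edge_prob = 0.4) {
  terms <- sprintf("T%02d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), terms)
  for (i in seq_len(n_terms)[-1]) {
    cand <- terms[seq_len(i - 1)]
    parents[[terms[i]]] <- cand[stats::runif(length(cand)) < edge_prob]
  }
  ontology_dag(terms, parents)
}

# Exhaustive minimum vertex-cut size by subset enumeration; NA when no cut
# exists (complete graphs).  Independent of find_separator's max-flow path.
brute_min_cut_size <- function(g) {
  verts <- igraph::V(g)$name
  n <- length(verts)
  for (m in seq_len(max(0, n - 2))) {
    subsets <- utils::combn(verts, m)
    for (j in seq_len(ncol(subsets))) {
      rest <- igraph::delete_vertices(g, subsets[, j])
      if (igraph::gorder(rest) >= 2 && !igraph::is_connected(rest)) return(m)
    }
  }
  NA_integer_
}
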