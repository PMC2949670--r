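#' Construct a protein-protein interaction graph
#'
#' A PPI network is modeled as a simple undirected graph `G = <V, E>` whose
#' vertices are protein identifiers (opaque, case-sensitive strings) and whose
#' edges are observed physical interactions.  The constructor enforces the
#' simple-graph invariants: self-loops are dropped, duplicate and reversed
#' duplicate edges collapse to a single undirected edge.  Isolated vertices
#' are permitted (real interaction screens report degree-0 proteins).
#'
#' @param edges a two-column matrix or data frame of vertex identifiers
#'   (additional columns are ignored), or `NULL` for an edgeless graph.
#' @param vertices optional character vector of vertex identifiers to include
#'   even when they touch no edge.
#' @return an [igraph::igraph] object: undirected, simple, with vertex names.
#' @examples
#' g <- ppi_graph(rbind(c("A", "B"), c("B", "A"), c("A", "A")), vertices = "C")
#' igraph::gorder(g)  # 3 vertices
#' igraph::gsize(g)   # 1 edge
#' @export
ppi_graph <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(), ncol = 2)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    em <- em[em[, 1] != em[, 2], , drop = FALSE]
  }
  verts <- unique(c(as.character(vertices), as.vector(t(em))))
  if (length(verts) == 0) {
    stop("no edges/vertices: cannot build an empty PPI graph without vertices")
  }
  d <- data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(d, directed = FALSE, vertices = verts)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Test whether an object is a usable PPI graph
#'
#' @param g object to test.
#' @return `TRUE` for an undirected, simple, vertex-named igraph.
#' @export
is_ppi_graph <- function(g) {
  igraph::is_igraph(g) &&
    !igraph::is_directed(g) &&
    igraph::is_simple(g) &&
    !is.null(igraph::V(g)$name)
}

#' Graph density
#'
#' The density of `G = <V, E>` is `2|E| / (|V| (|V| - 1))`, the fraction of
#' realized vertex pairs; it is 1 exactly for complete graphs.  Density is
#' deliberately undefined (an error, not 0) for fewer than two vertices so
#' that singleton artifacts are never silently scored.
#'
#' @param g a PPI graph.
#' @return density in `[0, 1]`.
#' @examples
#' ppi_density(make_complete_graph(4))  # 1
#' @export
ppi_density <- function(g) {
  n <- igraph::gorder(g)
  if (n < 2) stop("density undefined for graphs with fewer than 2 vertices")
  2 * igraph::gsize(g) / (n * (n - 1))
}

#' Cluster score
#'
#' The cluster score of a graph is its density multiplied by its vertex
#' count, i.e. `2|E| / (|V| - 1)`.  A connected graph is a tree if and only
#' if its cluster score equals 2, which is the basis of the optional
#' tree-excluding refinement filter in [cfa()].
#'
#' @inheritParams ppi_density
#' @return nonnegative real.
#' @examples
#' cluster_score(make_path_graph(5))      # 2: a path is a tree
#' cluster_score(make_complete_graph(4))  # 4
#' @export
cluster_score <- function(g) {
  ppi_density(g) * igraph::gorder(g)
}

#' Graph diameter
#'
#' Greatest shortest-path distance between any two vertices.  Defined as 0
#' for a single-vertex graph (the decomposition examines subgraphs before
#' the minimum-size filter applies); an error for disconnected input.
#'
#' @inheritParams ppi_density
#' @return nonnegative integer.
#' @export
ppi_diameter <- function(g) {
  n <- igraph::gorder(g)
  if (n == 0) stop("diameter undefined for the empty graph")
  if (n == 1) return(0L)
  if (!igraph::is_connected(g)) stop("diameter undefined for a disconnected graph")
  as.integer(max(igraph::distances(g)))
}

#' Induced subgraph on a vertex set
#'
#' Returns the subgraph `G[vs]` whose vertices are `vs` and whose edges are
#' all edges of `g` with both endpoints in `vs` — the operation used to
#' segregate the network by localization groups.
#'
#' @inheritParams ppi_density
#' @param vs character vector of vertex identifiers, all present in `g`.
#' @return a PPI graph.
#' @export
ppi_subgraph <- function(g, vs) {
  vs <- unique(as.character(vs))
  unknown <- setdiff(vs, igraph::V(g)$name)
  if (length(unknown) > 0) {
    stop("unknown vertex identifier(s): ", paste(unknown, collapse = ", "))
  }
  igraph::induced_subgraph(g, vs)
}

#' Mean degree
#'
#' `2|E| / |V|`, the network-level average number of interaction partners.
#'
#' @inheritParams ppi_density
#' @return nonnegative real.
#' @export
mean_degree <- function(g) {
  2 * igraph::gsize(g) / igraph::gorder(g)
}

#' Harmonic-mean F-measure
#'
#' `F = 2 P R / (P + R)`, defined as 0 when both precision and recall are 0.
#'
#' @param precision,recall fractions in `[0, 1]`.
#' @return fraction in `[0, 1]`.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Named complete, path, and ring graphs
#'
#' Convenience constructors used throughout examples and tests: complete
#' graph `K_n`, path `P_n`, and cycle `C_n` with vertex names `prefix1..n`.
#'
#' @param n number of vertices.
#' @param prefix vertex-name prefix.
#' @return a PPI graph.
#' @export
make_complete_graph <- function(n, prefix = "v") {
  v <- paste0(prefix, seq_len(n))
  if (n < 2) return(ppi_graph(NULL, vertices = v))
  ppi_graph(t(utils::combn(v, 2)))
}

#' @rdname make_complete_graph
#' @export
make_path_graph <- function(n, prefix = "v") {
  v <- paste0(prefix, seq_len(n))
  if (n < 2) return(ppi_graph(NULL, vertices = v))
  ppi_graph(cbind(v[-n], v[-1]))
}

#' @rdname make_complete_graph
#' @export
make_ring_graph <- function(n, prefix = "v") {
  stopifnot(n >= 3)
  v <- paste0(prefix, seq_len(n))
  ppi_graph(cbind(v, c(v[-1], v[1])))
}
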