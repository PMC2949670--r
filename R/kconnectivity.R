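#' Degree refinement (iterated pruning to the k-core)
#'
#' Removes every vertex of degree below `k`, repeating until none remains:
#' the result is the classical k-core, the maximal subgraph of minimum
#' degree `>= k`.  By Menger's theorem a vertex of degree below `k` cannot
#' belong to any k-connected subgraph, so pruning is lossless for the
#' decomposition; iterating to a fixpoint (rather than one pass) only
#' removes further vertices whose degree dropped below `k` during pruning.
#'
#' @param g a PPI graph.
#' @param k integer `>= 1`, the connectivity level.
#' @return the refined PPI graph (possibly with zero vertices).
#' @export
refine <- function(g, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be an integer >= 1")
  repeat {
    if (igraph::gorder(g) == 0) break
    deg <- igraph::degree(g)
    drop <- names(deg)[deg < k]
    if (length(drop) == 0) break
    g <- igraph::delete_vertices(g, drop)
  }
  g
}

#' Find a minimum vertex separator smaller than k
#'
#' Searches a connected graph `h` with more than `k` vertices for a vertex
#' set of size `< k` whose removal disconnects it.  The vertex connectivity
#' `kappa(h)` is computed by maximum flow; when `kappa(h) < k` a *minimum*
#' cut is returned, and among all minimum cuts the lexicographically
#' smallest vertex set (under sorted identifier order), which makes the
#' whole decomposition deterministic.  When no such cut exists the graph is
#' k-connected (Menger).
#'
#' @param h connected PPI graph with `|V| > k`.
#' @param k integer `>= 1`.
#' @return list with elements `found` (logical) and `separator` (sorted
#'   character vector, empty when `found` is `FALSE`).
#' @export
find_separator <- function(h, k) {
  if (!igraph::is_connected(h)) {
    stop("find_separator requires a connected graph")
  }
  n <- igraph::gorder(h)
  if (n <= k) stop("find_separator requires |V| > k")
  kappa <- igraph::vertex_connectivity(h)
  if (kappa >= k) {
    return(list(found = FALSE, separator = character()))
  }
  cuts <- lapply(igraph::min_separators(h), function(s) sort(igraph::as_ids(s)))
  keys <- vapply(cuts, paste, "", collapse = "\r")
  list(found = TRUE, separator = cuts[[order(keys)[1]]])
}

#' Fragment a connected graph into k-connected subgraphs
#'
#' The recursive fragmentation step: a connected graph with at most `k`
#' vertices yields nothing; a graph with no separator of size `< k` is
#' itself k-connected and is returned whole; otherwise a minimum separator
#' is removed and the procedure recurses on the resulting connected
#' components.  Two recursion variants are supported:
#'
#' * `mode = "readd"` (default) — each component is re-extended by the
#'   separator vertices (induced subgraph on component plus separator)
#'   before recursing.  This variant never loses a maximal k-connected
#'   subgraph that happens to contain a cut vertex of the surrounding
#'   graph, at the price of possibly overlapping outputs; it is the only
#'   variant whose output is guaranteed to contain every maximal
#'   k-connected subgraph.
#' * `mode = "literal"` — the separator vertices are discarded before
#'   recursing, exactly as in the classical pseudocode formulation.
#'   Simpler and overlap-free, but a k-connected subgraph containing a cut
#'   vertex of its surroundings is truncated or lost (e.g. in a bowtie the
#'   shared vertex is discarded and both triangles vanish).
#'
#' @param h connected PPI graph.
#' @param k integer `>= 1`.
#' @param mode separator handling, `"readd"` (default) or `"literal"`.
#' @return list of k-connected PPI graphs (possibly empty).
#' @export
decompose_kconnected <- function(h, k, mode = c("readd", "literal")) {
  mode <- match.arg(mode)
  if (!igraph::is_connected(h)) {
    stop("decompose_kconnected requires a connected graph")
  }
  if (igraph::gorder(h) <= k) return(list())
  sep <- find_separator(h, k)
  if (!sep$found) return(list(h))
  remainder <- igraph::delete_vertices(h, sep$separator)
  comps <- igraph::decompose(remainder)
  out <- list()
  for (comp in comps) {
    piece <- if (mode == "literal") {
      comp
    } else {
      igraph::induced_subgraph(h, c(igraph::V(comp)$name, sep$separator))
    }
    out <- c(out, decompose_kconnected(piece, k, mode))
  }
  out
}

#' Maximal k-connected subgraphs of a graph
#'
#' Applies [refine()] at level `k`, splits the refined graph into connected
#' components, and fragments each with [decompose_kconnected()]; the
#' concatenated results are the level-k candidate subgraphs.
#'
#' @inheritParams decompose_kconnected
#' @param g a PPI graph (connectivity not required).
#' @return list of k-connected PPI graphs.
#' @export
maximal_kconnected <- function(g, k, mode = c("readd", "literal")) {
  mode <- match.arg(mode)
  r <- refine(g, k)
  if (igraph::gorder(r) == 0) return(list())
  comps <- igraph::decompose(r)
  out <- lapply(comps, decompose_kconnected, k = k, mode = mode)
  do.call(c, out)
}

#' Brute-force k-connectivity oracle
#'
#' Checks the definition directly: `h` is k-connected iff `|V| > k` and the
#' removal of every vertex subset of size `< k` leaves a connected graph.
#' Exhaustive over all subsets, so restricted to at most 14 vertices; used
#' as an independent test oracle for the decomposition, never inside it.
#'
#' @param h a PPI graph.
#' @param k integer `>= 1`.
#' @return logical.
#' @export
verify_kconnected <- function(h, k) {
  n <- igraph::gorder(h)
  if (n > 14) stop("brute-force oracle restricted to graphs with at most 14 vertices")
  if (n <= k) return(FALSE)
  if (!igraph::is_connected(h)) return(FALSE)
  verts <- igraph::V(h)$name
  if (k >= 2) {
    for (m in seq_len(k - 1)) {
      subsets <- utils::combn(verts, m)
      for (j in seq_len(ncol(subsets))) {
        if (!igraph::is_connected(igraph::delete_vertices(h, subsets[, j]))) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}
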