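#' Configuration for the k-connected finding algorithm
#'
#' Bundles the tunable filtering parameters of [cfa()]:
#'
#' * `min_cluster_size` — clusters with fewer members are dropped (default 4;
#'   size-3 cliques are overwhelmingly not complexes).
#' * `diameter_limit_k1` — 1-connected candidates with diameter above this
#'   are dropped (default 4); level-k candidates (`k >= 2`) use `k` itself
#'   as the limit.
#' * `use_cluster_score_filter` — when `TRUE`, additionally drop level-k
#'   clusters whose cluster score is `<= k + 1`; at `k = 1` this removes
#'   exactly the tree-shaped clusters (score 2), which are the least
#'   reliable candidates in noisy two-hybrid data.  Off by default.
#' * `separator_mode` — separator handling during fragmentation, see
#'   [decompose_kconnected()].  The default `"readd"` is the variant that
#'   preserves every maximal k-connected subgraph; `"literal"` follows the
#'   classical pseudocode (separator vertices discarded) and can truncate
#'   or lose clusters that contain cut vertices of the wider network.
#' * `max_k` — optional cap on the connectivity sweep.
#'
#' @param min_cluster_size integer `>= 1`.
#' @param diameter_limit_k1 integer `>= 1`.
#' @param use_cluster_score_filter logical.
#' @param separator_mode `"readd"` (default) or `"literal"`.
#' @param max_k optional integer cap on k.
#' @return an object of class `cfa_config`.
#' @export
cfa_config <- function(min_cluster_size = 4L,
                       diameter_limit_k1 = 4L,
                       use_cluster_score_filter = FALSE,
                       separator_mode = c("readd", "literal"),
                       max_k = NULL) {
  separator_mode <- match.arg(separator_mode)
  min_cluster_size <- as.integer(min_cluster_size)
  diameter_limit_k1 <- as.integer(diameter_limit_k1)
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  if (diameter_limit_k1 < 1) stop("diameter_limit_k1 must be >= 1")
  structure(list(min_cluster_size = min_cluster_size,
                 diameter_limit_k1 = diameter_limit_k1,
                 use_cluster_score_filter = isTRUE(use_cluster_score_filter),
                 separator_mode = separator_mode,
                 max_k = if (is.null(max_k)) NULL else as.integer(max_k)),
            class = "cfa_config")
}

# Empty cluster table with the canonical columns.
empty_clusters <- function() {
  data.frame(name = character(), size = integer(),
             connectivity_level = integer(), density = numeric(),
             cluster_score = numeric(), diameter = integer(),
             members = I(list()), stringsAsFactors = FALSE)
}

# Deterministic sort: descending size, then lexicographic member sets.
sort_cluster_rows <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- vapply(df$members, function(m) paste(sort(m), collapse = "\r"), "")
  df <- df[order(-df$size, key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Finalize a cluster table: assign names after sorting.
finalize_clusters <- function(df) {
  df <- sort_cluster_rows(df)
  if (nrow(df) > 0) df$name <- sprintf("cluster_%03d", seq_len(nrow(df)))
  df
}

#' Predict protein complexes by k-connected subgraph decomposition
#'
#' The full prediction pipeline on one network.  For `k = 1, 2, ...` the
#' maximal k-connected candidate subgraphs are generated with
#' [maximal_kconnected()] until a level yields none (or `max_k` is hit).
#' Candidates are then filtered: level-1 subgraphs must have diameter at
#' most `diameter_limit_k1`; level-k subgraphs (`k >= 2`) diameter at most
#' `k`.  The union over all levels is deduplicated — a vertex set found at
#' several levels is kept once, annotated with the highest level at which
#' it appeared (its connectivity number) — and clusters smaller than
#' `min_cluster_size` are removed.  With `use_cluster_score_filter`,
#' level-k clusters with cluster score `<= k + 1` are also removed.
#'
#' @param g a PPI graph.
#' @param config a [cfa_config()] object.
#' @return a data frame with one row per predicted cluster and columns
#'   `name`, `size`, `connectivity_level`, `density`, `cluster_score`,
#'   `diameter`, and the list-column `members`, sorted by descending size
#'   then lexicographic member set.
#' @examples
#' g <- make_complete_graph(5)
#' cfa(g)  # one cluster of 5, connectivity level 4
#' @export
cfa <- function(g, config = cfa_config()) {
  stopifnot(inherits(config, "cfa_config"))
  if (is.null(g) || igraph::gorder(g) == 0) return(empty_clusters())
  records <- list()
  k <- 1L
  repeat {
    subs <- maximal_kconnected(g, k, mode = config$separator_mode)
    if (length(subs) == 0) break
    limit <- if (k == 1L) config$diameter_limit_k1 else k
    for (s in subs) {
      d <- ppi_diameter(s)
      if (d <= limit) {
        records[[length(records) + 1L]] <- list(graph = s, level = k, diameter = d)
      }
    }
    if (!is.null(config$max_k) && k >= config$max_k) break
    k <- k + 1L
  }
  if (length(records) == 0) return(empty_clusters())

  # Deduplicate identical vertex sets, keeping the highest level label.
  keys <- vapply(records, function(r) {
    paste(sort(igraph::V(r$graph)$name), collapse = "\r")
  }, "")
  best <- tapply(seq_along(records), keys, function(idx) {
    idx[which.max(vapply(records[idx], `[[`, 0L, "level"))]
  })
  records <- records[sort(as.integer(best))]

  rows <- lapply(records, function(r) {
    n <- igraph::gorder(r$graph)
    data.frame(name = NA_character_, size = n,
               connectivity_level = as.integer(r$level),
               density = if (n >= 2) ppi_density(r$graph) else NA_real_,
               cluster_score = if (n >= 2) cluster_score(r$graph) else NA_real_,
               diameter = as.integer(r$diameter),
               members = I(list(sort(igraph::V(r$graph)$name))),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$size >= config$min_cluster_size, , drop = FALSE]
  if (config$use_cluster_score_filter) {
    df <- df[df$cluster_score > df$connectivity_level + 1, , drop = FALSE]
  }
  finalize_clusters(df)
}
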