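#' Overlap score between a predicted cluster and a reference complex
#'
#' `Overlap(S, C) = |S ∩ C|^2 / (|S| |C|)`, the product of the two
#' containment fractions; symmetric, 1 exactly when the sets are equal, 0
#' when disjoint.  A cluster and a complex are said to match when their
#' overlap meets a threshold `theta` (conventionally 0.5).
#'
#' @param s,c non-empty character vectors (vertex sets).
#' @return fraction in `[0, 1]`.
#' @examples
#' overlap_score(letters[1:4], letters[2:7])  # 9 / 24
#' @export
overlap_score <- function(s, c) {
  s <- unique(s); c <- unique(c)
  if (length(s) == 0 || length(c) == 0) {
    stop("overlap score undefined for empty sets")
  }
  length(intersect(s, c))^2 / (length(s) * length(c))
}

#' Evaluate predicted clusters against a reference complex catalog
#'
#' Reference complexes are first restricted to the network: members absent
#' from `g` are removed, and complexes left with at most 3 members are
#' dropped (matching the convention that size-3-or-smaller complexes are
#' excluded from scoring).  Matching is many-to-many at threshold `theta`:
#' precision is the fraction of clusters matching at least one surviving
#' complex, recall the fraction of surviving complexes matched by at least
#' one cluster, and the F-measure their harmonic mean.
#'
#' @param predicted cluster data frame from [cfa()] or a list of member
#'   vectors.
#' @param reference named list of complex member sets.
#' @param theta overlap threshold in `(0, 1]`, default 0.5.
#' @param g the PPI graph the predictions were made on.
#' @return an object of class `cfa_evaluation`: a list with fields `theta`,
#'   `n_clusters`, `n_complexes`, `matched_clusters`, `matched_complexes`,
#'   `precision`, `recall`, `f_measure`, plus per-item logical vectors
#'   `cluster_matched` and `complex_matched`.
#' @export
evaluate_clusters <- function(predicted, reference, theta = 0.5, g) {
  if (!(theta > 0 && theta <= 1)) stop("theta must be in (0, 1]")
  pred <- cluster_members(predicted)
  verts <- igraph::V(g)$name
  ref <- lapply(reference, intersect, verts)
  ref <- ref[lengths(ref) > 3]

  n_s <- length(pred); n_c <- length(ref)
  cluster_matched <- logical(n_s)
  complex_matched <- logical(n_c)
  if (n_s > 0 && n_c > 0) {
    for (i in seq_len(n_s)) {
      for (j in seq_len(n_c)) {
        if (overlap_score(pred[[i]], ref[[j]]) >= theta) {
          cluster_matched[i] <- TRUE
          complex_matched[j] <- TRUE
        }
      }
    }
  }
  precision <- if (n_s == 0) 0 else sum(cluster_matched) / n_s
  recall <- if (n_c == 0) 0 else sum(complex_matched) / n_c
  structure(list(theta = theta,
                 n_clusters = n_s,
                 n_complexes = n_c,
                 matched_clusters = sum(cluster_matched),
                 matched_complexes = sum(complex_matched),
                 precision = precision,
                 recall = recall,
                 f_measure = f_measure(precision, recall),
                 cluster_matched = cluster_matched,
                 complex_matched = stats::setNames(complex_matched, names(ref))),
            class = "cfa_evaluation")
}

#' @export
print.cfa_evaluation <- function(x, ...) {
  cat(sprintf("Cluster/complex evaluation at theta = %g\n", x$theta))
  cat(sprintf("  clusters:  %d (%d matched)\n", x$n_clusters, x$matched_clusters))
  cat(sprintf("  complexes: %d (%d matched)\n", x$n_complexes, x$matched_complexes))
  cat(sprintf("  precision %.3f  recall %.3f  F %.3f\n",
              x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Precision/recall/F curve over a grid of overlap thresholds
#'
#' @inheritParams evaluate_clusters
#' @param thetas numeric vector of thresholds in `(0, 1]`.
#' @return data frame with columns `theta`, `precision`, `recall`,
#'   `f_measure`.
#' @export
f_curve <- function(predicted, reference, g, thetas = seq(0.1, 1, by = 0.1)) {
  rows <- lapply(thetas, function(th) {
    ev <- evaluate_clusters(predicted, reference, theta = th, g = g)
    data.frame(theta = th, precision = ev$precision,
               recall = ev$recall, f_measure = ev$f_measure)
  })
  do.call(rbind, rows)
}

#' Connectivity score of a complex set on a network
#'
#' Measures how much of each reference complex survives as a k-connected
#' unit inside the network: for each complex `c`, the maximal k-connected
#' subgraphs of the induced subgraph `G[c]` are computed (no diameter or
#' size filtering — the score characterizes the complexes, not the
#' predictions) and the size of the largest one is taken (0 when none
#' exists).  The score is the sum of these maxima divided by the total
#' number of complex members with at least one intra-complex interaction.
#'
#' @param complexes named list of complex member sets.
#' @param g a PPI graph.
#' @param k connectivity level, integer `>= 1`.
#' @param mode separator handling, see [decompose_kconnected()].
#' @return fraction in `[0, 1]`.
#' @export
kscore <- function(complexes, g, k, mode = c("readd", "literal")) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1")
  verts <- igraph::V(g)$name
  num <- 0; den <- 0
  for (cx in complexes) {
    vs <- intersect(cx, verts)
    if (length(vs) == 0) next
    sub <- ppi_subgraph(g, vs)
    den_c <- sum(igraph::degree(sub) > 0)
    subs <- maximal_kconnected(sub, k, mode = mode)
    num_c <- if (length(subs) > 0) max(vapply(subs, igraph::gorder, numeric(1))) else 0
    num <- num + num_c
    den <- den + den_c
  }
  if (den == 0) stop("kscore undefined: no complex member has an intra-complex edge")
  num / den
}

#' Remove redundant (highly overlapping) clusters
#'
#' Greedy sweep over the clusters in canonical order (descending size, ties
#' broken lexicographically on the member set): a cluster is kept only if
#' its overlap score with every already-kept cluster is below `alpha`, so of
#' two heavily overlapping clusters the larger survives.  With `alpha = 1`
#' only exact duplicates are removed.
#'
#' @param clusters cluster data frame from [cfa()].
#' @param alpha overlap threshold in `(0, 1]`, default 0.5.
#' @return the surviving rows, in canonical order, renamed.
#' @export
remove_redundant <- function(clusters, alpha = 0.5) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  df <- sort_cluster_rows(clusters)
  if (nrow(df) <= 1) return(finalize_clusters(df))
  kept <- integer()
  for (i in seq_len(nrow(df))) {
    conflict <- any(vapply(kept, function(j) {
      overlap_score(df$members[[i]], df$members[[j]]) >= alpha
    }, logical(1)))
    if (!conflict) kept <- c(kept, i)
  }
  finalize_clusters(df[kept, , drop = FALSE])
}
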