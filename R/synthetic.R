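# Run code under a temporary RNG state seeded explicitly; the caller's
# global .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a planted-core benchmark graph
#'
#' Describes a synthetic PPI network with known ground truth: `n_cores`
#' vertex-disjoint cores, each `target_k`-connected by construction, plus
#' isolated background vertices and uniform inter-core/background noise
#' edges.  Core kinds:
#'
#' * `"complete"` — complete graphs `K_{core_size}` (connectivity
#'   `core_size - 1 >= target_k`).
#' * `"cycle_chord"` — circulant (Harary-style) graphs: a ring where every
#'   vertex is joined to its nearest neighbors on each side up to the
#'   degree needed for `target_k`-connectivity, plus a few random chords.
#' * `"random_kconn"` — Erdős–Rényi graphs rejection-sampled until the
#'   connectivity oracle certifies them `target_k`-connected.
#'
#' @param n_cores number of planted cores.
#' @param core_size vertices per core; must exceed `target_k`.
#' @param core_kind `"complete"`, `"cycle_chord"`, or `"random_kconn"`.
#' @param target_k connectivity each core must attain.
#' @param background_vertices number of extra vertices outside all cores.
#' @param noise_edge_prob probability in `[0, 1)` of each possible edge not
#'   internal to a single core.
#' @param seed integer RNG seed; every realization is reproducible from it.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(n_cores = 5L, core_size = 6L,
                       core_kind = c("complete", "cycle_chord", "random_kconn"),
                       target_k = 4L, background_vertices = 30L,
                       noise_edge_prob = 0.02, seed = 13L) {
  core_kind <- match.arg(core_kind)
  if (core_size <= target_k) stop("core_size must exceed target_k")
  if (!(noise_edge_prob >= 0 && noise_edge_prob < 1)) {
    stop("noise_edge_prob must be in [0, 1)")
  }
  structure(list(n_cores = as.integer(n_cores), core_size = as.integer(core_size),
                 core_kind = core_kind, target_k = as.integer(target_k),
                 background_vertices = as.integer(background_vertices),
                 noise_edge_prob = noise_edge_prob, seed = as.integer(seed)),
            class = "plant_spec")
}

# Certify a core graph target_k-connected: exhaustive oracle at small
# sizes, max-flow vertex connectivity beyond the oracle's 14-vertex guard.
core_is_kconnected <- function(g, k) {
  if (igraph::gorder(g) <= 14) {
    verify_kconnected(g, k)
  } else {
    igraph::gorder(g) > k && igraph::vertex_connectivity(g) >= k
  }
}

# Edge matrix for one core on the given vertex names.
make_core_edges <- function(verts, kind, target_k) {
  n <- length(verts)
  if (kind == "complete") {
    return(t(utils::combn(verts, 2)))
  }
  if (kind == "cycle_chord") {
    # circulant: connect offsets 1..ceiling(target_k / 2); for odd target_k
    # this overshoots by one, which can only raise connectivity
    reach <- max(1L, as.integer(ceiling(target_k / 2)))
    em <- do.call(rbind, lapply(seq_len(reach), function(d) {
      cbind(verts, verts[(seq_len(n) + d - 1L) %% n + 1L])
    }))
    em <- em[em[, 1] != em[, 2], , drop = FALSE]
    # a couple of random chords for topological variety
    pool <- t(utils::combn(verts, 2))
    key <- paste(pmin(pool[, 1], pool[, 2]), pmax(pool[, 1], pool[, 2]))
    used <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    free <- pool[!(key %in% used), , drop = FALSE]
    if (nrow(free) > 0) {
      extra <- free[sample.int(nrow(free), min(2L, nrow(free))), , drop = FALSE]
      em <- rbind(em, extra)
    }
    return(em)
  }
  # random_kconn: rejection sampling at a density comfortably above the
  # connectivity threshold
  p <- min(0.95, (target_k + 1.5) / n)
  for (try in seq_len(200L)) {
    pool <- t(utils::combn(verts, 2))
    em <- pool[stats::runif(nrow(pool)) < p, , drop = FALSE]
    if (nrow(em) == 0) next
    g <- ppi_graph(em, vertices = verts)
    if (core_is_kconnected(g, target_k)) return(em)
    p <- min(0.98, p * 1.15)
  }
  stop("failed to sample a ", target_k, "-connected core after 200 attempts")
}

#' Generate a planted-core benchmark network
#'
#' Builds the network described by a [plant_spec()]: each core is
#' constructed on its own vertices (`C<i>_P<j>`), certified
#' `target_k`-connected, background vertices (`B<j>`) are added, and every
#' vertex pair not internal to a single core receives a noise edge with
#' probability `noise_edge_prob`.  The cores double as the ground-truth
#' reference complexes.  Fully reproducible from `spec$seed`.
#'
#' @param spec a [plant_spec()].
#' @return list with elements `graph` (PPI graph) and `complexes` (named
#'   list of the planted core member sets).
#' @export
generate_planted_graph <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    core_verts <- lapply(seq_len(spec$n_cores), function(i) {
      sprintf("C%d_P%02d", i, seq_len(spec$core_size))
    })
    core_edges <- lapply(core_verts, make_core_edges,
                         kind = spec$core_kind, target_k = spec$target_k)
    for (i in seq_along(core_edges)) {
      g_core <- ppi_graph(core_edges[[i]], vertices = core_verts[[i]])
      if (!core_is_kconnected(g_core, spec$target_k)) {
        stop("core ", i, " failed ", spec$target_k, "-connectivity certification")
      }
    }
    bg <- if (spec$background_vertices > 0) {
      sprintf("B%02d", seq_len(spec$background_vertices))
    } else character()
    all_verts <- c(unlist(core_verts), bg)
    core_of <- stats::setNames(rep(c(seq_len(spec$n_cores), 0L),
                                   c(lengths(core_verts), length(bg))), all_verts)
    edges <- do.call(rbind, core_edges)
    if (spec$noise_edge_prob > 0 && length(all_verts) >= 2) {
      pool <- t(utils::combn(all_verts, 2))
      intra <- core_of[pool[, 1]] != 0L & core_of[pool[, 1]] == core_of[pool[, 2]]
      pool <- pool[!intra, , drop = FALSE]
      noise <- pool[stats::runif(nrow(pool)) < spec$noise_edge_prob, , drop = FALSE]
      edges <- rbind(edges, noise)
    }
    list(graph = ppi_graph(edges, vertices = all_verts),
         complexes = stats::setNames(core_verts,
                                     sprintf("core_%d", seq_len(spec$n_cores))))
  })
}

#' Generate a toy ontology with groups straddling an informativeness level
#'
#' Builds a two-level cellular-component ontology — one root with
#' `n_groups` children — and annotates `proteins_per_group` distinct
#' proteins directly to each child.  At any threshold not exceeding
#' `proteins_per_group`, the informative terms are exactly the children
#' (each meets the threshold while having no descendants; the root is
#' excluded because its children meet the threshold).
#'
#' @param n_groups number of child terms.
#' @param proteins_per_group direct annotations per child; must be at least
#'   `threshold`.
#' @param threshold informativeness threshold the fixture is built for.
#' @param seed RNG seed (controls the protein-to-group assignment order).
#' @return list with elements `dag` (an [ontology_dag()]), `ann` (direct
#'   annotation list), and `threshold`.
#' @export
generate_toy_ontology <- function(n_groups = 3L, proteins_per_group = 12L,
                                  threshold = 10L, seed = 1L) {
  if (proteins_per_group < threshold) {
    stop("proteins_per_group must be at least threshold")
  }
  with_seed(seed, {
    root <- "GO:0000001"
    children <- sprintf("GO:%07d", seq_len(n_groups) + 1L)
    dag <- ontology_dag(c(root, children),
                        parents = stats::setNames(rep(list(root), n_groups),
                                                  children))
    prots <- sprintf("P%03d", seq_len(n_groups * proteins_per_group))
    prots <- sample(prots)
    assign_to <- rep(children, each = proteins_per_group)
    ann <- stats::setNames(as.list(assign_to), prots)
    list(dag = dag, ann = ann[order(names(ann))], threshold = as.integer(threshold))
  })
}
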