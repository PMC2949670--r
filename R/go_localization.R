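#' Construct an ontology DAG
#'
#' A minimal rooted-DAG container for Gene Ontology cellular-component
#' terms: a set of term identifiers and, for each, its parent terms via
#' `is_a`/`part_of` relations.  Cycles and dangling parent references are
#' rejected.
#'
#' @param terms character vector of term identifiers.
#' @param parents named list mapping each term to a character vector of its
#'   parent terms (terms absent from the list have no parents).
#' @param term_names optional named character vector of human-readable term
#'   labels.
#' @return an object of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, parents = list(), term_names = NULL) {
  terms <- unique(as.character(terms))
  parents <- parents[names(parents) %in% terms]
  full <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    p <- unique(as.character(parents[[t]]))
    unknown <- setdiff(p, terms)
    if (length(unknown) > 0) {
      stop("parent term(s) not in ontology: ", paste(unknown, collapse = ", "))
    }
    full[[t]] <- setdiff(p, t)
  }
  dag <- structure(list(terms = terms, parents = full, term_names = term_names),
                   class = "ontology_dag")
  # Acyclicity: every term must reach only ancestors, never itself.
  anc <- dag_ancestors(dag)
  cyc <- names(anc)[mapply(function(t, a) t %in% a, names(anc), anc)]
  if (length(cyc) > 0) {
    stop("ontology contains a cycle through: ", paste(cyc, collapse = ", "))
  }
  dag
}

# All proper ancestors of every term (memoized depth-first closure).
dag_ancestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  visit <- function(t, stack = character()) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (t %in% stack) return(stack)  # cycle: report path back to the term
    p <- dag$parents[[t]]
    out <- p
    for (q in p) out <- union(out, visit(q, c(stack, t)))
    memo[[t]] <- out
    out
  }
  stats::setNames(lapply(dag$terms, visit), dag$terms)
}

# All proper descendants of every term.
dag_descendants <- function(dag) {
  anc <- dag_ancestors(dag)
  desc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in names(anc)) {
    for (a in anc[[t]]) desc[[a]] <- c(desc[[a]], t)
  }
  lapply(desc, function(x) unique(as.character(x)))
}

#' Read a minimal OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas keeping `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of`; other relationship types and obsolete terms are
#' ignored.  When `namespace` is non-`NULL`, terms carrying a different
#' namespace are dropped (terms without a namespace field are kept).
#'
#' @param path OBO file path.
#' @param namespace namespace filter, default `"cellular_component"`; use
#'   `NULL` to keep everything.
#' @return an [ontology_dag()].
#' @export
read_obo <- function(path, namespace = "cellular_component") {
  lines <- readLines(path)
  ids <- character(); nms <- character()
  parents <- list(); spaces <- character(); obsolete <- logical()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    ids <<- c(ids, cur$id)
    nms <<- c(nms, cur$name %||% NA_character_)
    parents[[cur$id]] <<- unique(cur$parents)
    spaces <<- c(spaces, cur$namespace %||% NA_character_)
    obsolete <<- c(obsolete, isTRUE(cur$obsolete))
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)          # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character()); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    kv <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) < 3) next
    key <- kv[2]; val <- trimws(kv[3])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$parents <- c(cur$parents, strsplit(val, "\\s+")[[1]][1])
    else if (key == "relationship") {
      f <- strsplit(val, "\\s+")[[1]]
      if (length(f) >= 2 && f[1] == "part_of") cur$parents <- c(cur$parents, f[2])
    }
    else if (key == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
  }
  flush()
  keep <- !obsolete
  if (!is.null(namespace)) keep <- keep & (is.na(spaces) | spaces == namespace)
  ids_k <- ids[keep]
  parents_k <- lapply(parents[ids_k], function(p) intersect(p, ids_k))
  names(parents_k) <- ids_k
  ontology_dag(ids_k, parents_k, term_names = stats::setNames(nms[keep], ids_k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read protein-to-term annotations
#'
#' Accepts GAF 2.x (column 2 = protein identifier, column 5 = GO term,
#' column 9 = aspect, filtered to `C`) or a plain two-column TSV of protein
#' and term.  `format = "auto"` treats files whose data lines carry 10 or
#' more tab-separated fields (or that contain `!` headers) as GAF.
#'
#' @param path annotation file path.
#' @param format `"auto"`, `"gaf"` or `"tsv"`.
#' @return a named list mapping protein identifiers to character vectors of
#'   directly assigned terms.
#' @export
read_annotations <- function(path, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  data <- lines[!grepl("^\\s*(!|#|$)", lines)]
  if (length(data) == 0) return(stats::setNames(list(), character()))
  fields <- strsplit(data, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (any(grepl("^!", lines)) || max(lengths(fields)) >= 10) "gaf" else "tsv"
  }
  if (format == "gaf") {
    ok <- lengths(fields) >= 9
    fields <- fields[ok]
    prot <- vapply(fields, `[`, "", 2L)
    term <- vapply(fields, `[`, "", 5L)
    aspect <- vapply(fields, `[`, "", 9L)
    sel <- aspect == "C"
    prot <- prot[sel]; term <- term[sel]
  } else {
    fields <- lapply(data, function(l) strsplit(trimws(l), "[\t ]+", perl = TRUE)[[1]])
    bad <- which(lengths(fields) < 2)
    if (length(bad) > 0) stop(sprintf("malformed annotation line: %s", data[bad[1]]))
    prot <- vapply(fields, `[`, "", 1L)
    term <- vapply(fields, `[`, "", 2L)
  }
  split(term, prot) |> lapply(unique)
}

#' Write a minimal OBO file
#'
#' Inverse of [read_obo()] for synthetic ontologies: emits one `[Term]`
#' stanza per term with `is_a` parent lines and the cellular-component
#' namespace.
#'
#' @param dag an [ontology_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    nm <- if (!is.null(dag$term_names) && !is.na(dag$term_names[t])) {
      dag$term_names[[t]]
    } else t
    writeLines(c("[Term]", paste0("id: ", t), paste0("name: ", nm),
                 "namespace: cellular_component",
                 paste0("is_a: ", dag$parents[[t]]), ""), con)
  }
  invisible(path)
}

#' Write a two-column annotation table
#'
#' @param ann named list mapping proteins to term vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in names(ann)) {
    writeLines(paste(p, ann[[p]], sep = "\t"), con)
  }
  invisible(path)
}

#' Propagate annotations up the ontology
#'
#' Closes each protein's term set under ancestor traversal: annotation to a
#' term implies annotation to all its `is_a`/`part_of` ancestors, the
#' standard GO counting convention.  Idempotent.
#'
#' @param dag an [ontology_dag()].
#' @param ann named list of direct annotations (protein -> terms).
#' @return annotation list with ancestor-closed term sets.
#' @export
propagate_annotations <- function(dag, ann) {
  anc <- dag_ancestors(dag)
  lapply(ann, function(terms) {
    unknown <- setdiff(terms, dag$terms)
    if (length(unknown) > 0) {
      stop("annotation to unknown term(s): ", paste(unknown, collapse = ", "))
    }
    sort(unique(c(terms, unlist(anc[terms], use.names = FALSE))))
  })
}

# Number of proteins annotated (post-propagation) with each term.
term_counts <- function(dag, ann_propagated) {
  counts <- stats::setNames(integer(length(dag$terms)), dag$terms)
  tab <- table(unlist(ann_propagated, use.names = FALSE))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Informative ontology terms
#'
#' A term is informative at a threshold when at least `threshold` proteins
#' are annotated with it while every proper descendant annotates fewer than
#' `threshold` proteins — the most specific terms still backed by enough
#' proteins to be statistically useful.  The returned family never contains
#' a term together with one of its descendants.
#'
#' @param dag an [ontology_dag()].
#' @param ann named annotation list; propagated internally (idempotent), so
#'   direct or propagated annotations may be supplied.
#' @param threshold integer `>= 1`; 10 is the conventional choice for yeast
#'   cellular-component analysis.
#' @return character vector of informative term identifiers.
#' @export
informative_terms <- function(dag, ann, threshold = 10L) {
  threshold <- as.integer(threshold)
  if (threshold < 1) stop("threshold must be >= 1")
  annp <- propagate_annotations(dag, ann)
  counts <- term_counts(dag, annp)
  desc <- dag_descendants(dag)
  ok <- vapply(dag$terms, function(t) {
    counts[[t]] >= threshold &&
      all(counts[desc[[t]]] < threshold)
  }, logical(1))
  sort(dag$terms[ok])
}

#' Localization groups from informative terms
#'
#' One group per informative cellular-component term: the set of proteins
#' annotated (after propagation) with that term.  Groups may overlap, since
#' a protein can be annotated to several informative terms.
#'
#' @inheritParams informative_terms
#' @return named list mapping informative terms to protein sets.
#' @export
localization_groups <- function(dag, ann, threshold = 10L) {
  annp <- propagate_annotations(dag, ann)
  info <- informative_terms(dag, annp, threshold)
  groups <- lapply(info, function(t) {
    sort(names(annp)[vapply(annp, function(ts) t %in% ts, logical(1))])
  })
  stats::setNames(groups, info)
}

#' Segregate a network by localization groups and predict on each part
#'
#' For each localization group `L_i`, runs [cfa()] on the induced subgraph
#' `G[L_i]` (group members absent from the network are intersected away),
#' then unions the per-group predictions.  Duplicate vertex sets arising
#' from overlapping groups are collapsed, keeping the record with the
#' highest connectivity level.
#'
#' @param g a PPI graph.
#' @param groups named list of protein sets (see [localization_groups()]).
#' @param config a [cfa_config()].
#' @return a cluster data frame in the same format as [cfa()].
#' @export
segregate_and_run <- function(g, groups, config = cfa_config()) {
  parts <- lapply(groups, function(L) {
    vs <- intersect(L, igraph::V(g)$name)
    if (length(vs) == 0) return(empty_clusters())
    cfa(ppi_subgraph(g, vs), config)
  })
  df <- do.call(rbind, c(parts, list(empty_clusters())))
  if (nrow(df) == 0) return(empty_clusters())
  keys <- vapply(df$members, function(m) paste(sort(m), collapse = "\r"), "")
  best <- tapply(seq_len(nrow(df)), keys, function(idx) {
    idx[which.max(df$connectivity_level[idx])]
  })
  finalize_clusters(df[sort(as.integer(best)), , drop = FALSE])
}

#' Co-localization score of a complex set
#'
#' For each complex `c`, the largest number of its proteins falling in a
#' single localization group, divided (as a weighted average over all
#' complexes) by the number of its proteins belonging to any group:
#' `locscore = sum_c max_i |c ∩ L_i| / sum_c |{p in c : p in some L_i}|`.
#' Complexes with no annotated member contribute to neither sum.
#'
#' @param complexes named list of complex member sets.
#' @param groups named list of localization groups.
#' @return fraction in `(0, 1]`.
#' @export
locscore <- function(complexes, groups) {
  pool <- unique(unlist(groups, use.names = FALSE))
  num <- 0; den <- 0
  for (cx in complexes) {
    annotated <- sum(cx %in% pool)
    if (annotated == 0) next
    best <- max(vapply(groups, function(L) length(intersect(cx, L)), 0L))
    num <- num + best
    den <- den + annotated
  }
  if (den == 0) stop("locscore undefined: no complex has annotated members")
  num / den
}
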