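#' Read a PPI network from an edge-list file
#'
#' Reads a two-column (or wider) delimited text file of interactor pairs, the
#' reduced form of BioGRID-style tabular exports: columns 1 and 2 are the
#' interactor identifiers, any further columns are ignored.  Comment lines
#' starting with `#` and blank lines are skipped.  Duplicate lines and
#' reversed duplicates collapse to one undirected edge; self-loop lines are
#' dropped and their count reported via [message()].
#'
#' @param path file path or connection.
#' @param delimiter field-separator regular expression; the default splits on
#'   runs of tabs and/or spaces.
#' @return a PPI graph (see [ppi_graph()]).
#' @export
read_edge_list <- function(path, delimiter = "[\t ]+") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no edges/vertices: input contains no data lines")
  fields <- strsplit(trimws(lines[idx]), delimiter, perl = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d: expected at least 2 fields, got %d",
                 idx[bad[1]], lengths(fields)[bad[1]]))
  }
  em <- t(vapply(fields, function(f) f[1:2], character(2)))
  n_loops <- sum(em[, 1] == em[, 2])
  if (n_loops > 0) message(sprintf("dropped %d self-loop line(s)", n_loops))
  ppi_graph(em)
}

#' Read a reference complex catalog
#'
#' One complex per line: an optional leading name field followed by
#' tab/space-separated protein identifiers (MIPS/Aloy-style flat catalogs).
#' Comment (`#`) and blank lines are ignored.
#'
#' @param path file path or connection.
#' @param named if `TRUE` (default) the first field of each line is the
#'   complex name; otherwise all fields are members and names are generated.
#' @param delimiter field-separator regular expression.
#' @return a named list of character vectors (the complex member sets).
#' @export
read_complexes <- function(path, named = TRUE, delimiter = "[\t ]+") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(stats::setNames(list(), character()))
  fields <- strsplit(trimws(lines[idx]), delimiter, perl = TRUE)
  min_fields <- if (named) 2L else 1L
  bad <- which(lengths(fields) < min_fields)
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d: expected at least %d field(s)",
                 idx[bad[1]], min_fields))
  }
  if (named) {
    nms <- vapply(fields, `[`, "", 1L)
    members <- lapply(fields, function(f) unique(f[-1L]))
  } else {
    nms <- sprintf("complex_%03d", seq_along(fields))
    members <- lapply(fields, unique)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate complex name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  stats::setNames(members, nms)
}

#' Write predicted clusters to a file
#'
#' Writes the same dialect as the complex catalog (name followed by members,
#' tab-separated), preceded per cluster by a `#` comment line that records
#' its connectivity level, density, cluster score and diameter.  The output
#' is byte-deterministic for a given cluster table.
#'
#' @param clusters a cluster table as returned by [cfa()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# cfanet clusters: one complex per line; name\\tmembers...", con)
  for (i in seq_len(nrow(clusters))) {
    writeLines(sprintf("# %s\tk=%d\tsize=%d\tdensity=%.6g\tcluster_score=%.6g\tdiameter=%d",
                       clusters$name[i], clusters$connectivity_level[i],
                       clusters$size[i], clusters$density[i],
                       clusters$cluster_score[i], clusters$diameter[i]), con)
    writeLines(paste(c(clusters$name[i], sort(clusters$members[[i]])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a reference complex catalog
#'
#' @param complexes named list of character vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(complexes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(complexes)) {
    writeLines(paste(c(nm, sort(complexes[[nm]])), collapse = "\t"), con)
  }
  invisible(path)
}

# Normalize "a set of predicted clusters" to a plain list of member vectors.
# Accepts the cluster data frame produced by cfa() or a (possibly named)
# list of character vectors, e.g. from read_complexes().
cluster_members <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(x$members, x$name)
  } else if (is.list(x)) {
    x
  } else {
    stop("expected a cluster data frame or a list of member vectors")
  }
}
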