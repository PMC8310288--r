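#' Build the bipartite infection network
#'
#' One node per host and per phage, one edge per 1-cell of the matrix; node
#' degrees equal the matrix margins.
#'
#' @param mat filtered binary hosts x phages matrix.
#' @return Object of class `pbin_graph`: `host_nodes`, `phage_nodes`,
#'   `edges` (data.frame `host`, `phage`), `host_degree`, `phage_degree`.
#' @export
build_graph <- function(mat) {
  mat <- .validate_pbim(mat)
  idx <- which(mat == 1L, arr.ind = TRUE)
  structure(list(host_nodes = rownames(mat), phage_nodes = colnames(mat),
                 edges = data.frame(host = rownames(mat)[idx[, 1]],
                                    phage = colnames(mat)[idx[, 2]]),
                 host_degree = rowSums(mat), phage_degree = colSums(mat),
                 matrix = mat),
            class = "pbin_graph")
}

#' @export
print.pbin_graph <- function(x, ...) {
  cat(sprintf("bipartite infection network: %d hosts + %d phages, %d edges\n",
              length(x$host_nodes), length(x$phage_nodes), nrow(x$edges)))
  invisible(x)
}

#' Degree-sort an infection matrix
#'
#' Rows and columns are ordered by decreasing degree (ties broken by
#' original label order), the arrangement used to inspect nestedness
#' visually. Cell values are untouched, so NODF is unchanged.
#'
#' @param mat binary hosts x phages matrix.
#' @return The rearranged matrix.
#' @export
rearrange_matrix <- function(mat) {
  mat <- .validate_pbim(mat)
  prov <- attr(mat, "provenance")
  out <- mat[order(-rowSums(mat), seq_len(nrow(mat))),
             order(-colSums(mat), seq_len(ncol(mat))), drop = FALSE]
  attr(out, "provenance") <- paste0(prov %||% "", "; degree-sorted")
  out
}

#' Maximal bicliques of the infection network
#'
#' In a bipartite graph no mixed triangle exists, so the "fully connected,
#' edge density 1" cluster concept is the *biclique*: a host subset and a
#' phage subset with every cross pair an edge. This enumerates all maximal
#' bicliques exactly, by closing every subset of the smaller side (capped
#' at 16 entities on that side), then filters by the size thresholds.
#' Default thresholds of 2 x 2 suppress trivial star cliques.
#'
#' @param graph a [build_graph()] result or a binary matrix.
#' @param min_hosts,min_phages minimum subset sizes (>= 1).
#' @return Object of class `clique_set`: `cliques` (list of
#'   `list(hosts, phages)`, ordered by total size decreasing then labels),
#'   `definition = "maximal_biclique"`, and the thresholds.
#' @export
find_cliques <- function(graph, min_hosts = 2, min_phages = 2) {
  mat <- if (inherits(graph, "pbin_graph")) graph$matrix else .validate_pbim(graph)
  if (min_hosts < 1 || min_phages < 1) stop("minimum sizes must be >= 1")
  flipped <- nrow(mat) < ncol(mat)
  x <- if (flipped) t(mat) else mat             # enumerate subsets of columns of x
  C <- ncol(x)
  if (C > 16)
    stop("exact biclique enumeration supports at most 16 entities on the smaller side")
  seen <- new.env(hash = TRUE)
  cliques <- list()
  for (s in seq_len(bitwShiftL(1L, C) - 1L)) {
    cols <- which(bitwAnd(s, bitwShiftL(1L, seq_len(C) - 1L)) != 0L)
    rows <- which(rowSums(x[, cols, drop = FALSE]) == length(cols))
    if (length(rows) == 0) next
    closed <- which(colSums(x[rows, , drop = FALSE]) == length(rows))
    key <- paste(closed, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    hosts <- if (flipped) colnames(x)[closed] else rownames(x)[rows]
    phages <- if (flipped) rownames(x)[rows] else colnames(x)[closed]
    if (length(hosts) >= min_hosts && length(phages) >= min_phages)
      cliques[[length(cliques) + 1L]] <- list(hosts = sort(hosts),
                                              phages = sort(phages))
  }
  ord <- order(-vapply(cliques, function(cl) length(cl$hosts) + length(cl$phages), 0),
               vapply(cliques, function(cl) cl$hosts[1], ""),
               vapply(cliques, function(cl) cl$phages[1], ""))
  structure(list(cliques = cliques[ord], definition = "maximal_biclique",
                 min_hosts = min_hosts, min_phages = min_phages),
            class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat(sprintf("%d maximal biclique(s) (>= %d hosts x >= %d phages)\n",
              length(x$cliques), x$min_hosts, x$min_phages))
  for (cl in x$cliques)
    cat(sprintf("  %d hosts x %d phages: {%s} x {%s}\n",
                length(cl$hosts), length(cl$phages),
                paste(cl$hosts, collapse = ","), paste(cl$phages, collapse = ",")))
  invisible(x)
}

#' Export the network for external viewers
#'
#' `export_edgelist` writes a TSV of (host_id, phage_id) pairs;
#' `as_igraph` converts to a bipartite igraph object (vertex attributes
#' `type`, `degree`); `export_graphml` writes GraphML via igraph.
#'
#' @param graph a [build_graph()] result.
#' @param file output path.
#' @return `as_igraph` returns the igraph object; the writers return the
#'   path invisibly.
#' @export
export_edgelist <- function(graph, file) {
  stopifnot(inherits(graph, "pbin_graph"))
  utils::write.table(graph$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("host_id", "phage_id"))
  invisible(file)
}

#' @rdname export_edgelist
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "pbin_graph"))
  vertices <- data.frame(
    name = c(graph$host_nodes, graph$phage_nodes),
    type = rep(c(FALSE, TRUE), c(length(graph$host_nodes), length(graph$phage_nodes))),
    degree = c(unname(graph$host_degree), unname(graph$phage_degree)))
  igraph::graph_from_data_frame(graph$edges, directed = FALSE, vertices = vertices)
}

#' @rdname export_edgelist
#' @export
export_graphml <- function(graph, file) {
  igraph::write_graph(as_igraph(graph), file, format = "graphml")
  invisible(file)
}
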