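# Directed-graph centralities on the support of the adjacency matrix:
# sinks (in-degree), sources (out-degree, closeness) and cascade catalysts
# (betweenness).

support_graph <- function(a, self_loops = TRUE) {
  stopifnot(inherits(a, "reduced_adjacency"))
  m <- (unclass(a) > 0) * 1
  if (!self_loops) diag(m) <- 0
  igraph::graph_from_adjacency_matrix(m, mode = "directed", diag = self_loops)
}

#' Degree centralities
#'
#' In-degree of peril j counts the distinct perils that can trigger it
#' (non-zero column entries); out-degree of peril i counts the distinct
#' perils it can trigger (non-zero row entries). A self-loop counts once in
#' each.
#'
#' @param a A `reduced_adjacency`.
#' @param self_loops Count self-loops (default `TRUE`).
#' @return List with named integer vectors `in_degree` and `out_degree`.
#' @export
degree_centralities <- function(a, self_loops = TRUE) {
  stopifnot(inherits(a, "reduced_adjacency"))
  m <- unclass(a) > 0
  if (!self_loops) diag(m) <- FALSE
  ind <- colSums(m); outd <- rowSums(m)
  storage.mode(ind) <- "integer"; storage.mode(outd) <- "integer"
  list(in_degree = ind, out_degree = outd)
}

#' Harmonic closeness centrality (outgoing)
#'
#' Average reciprocal shortest-path length from each peril to every other
#' peril on the unweighted support graph, with unreachable perils
#' contributing 0: c(i) = (1/(n-1)) * sum_j 1/d(i, j). The harmonic form is
#' used because the empirical cascade graph is not strongly connected, so
#' plain average path length is undefined for some sources; high values
#' mark the main triggering perils.
#'
#' @param a A `reduced_adjacency`.
#' @return Named numeric vector in \[0, 1\].
#' @export
closeness_centrality <- function(a) {
  g <- support_graph(a, self_loops = FALSE)
  igraph::harmonic_centrality(g, mode = "out", normalized = TRUE)
}

#' Betweenness centrality
#'
#' Sum over ordered pairs (s, t), s != v != t, of the fraction of shortest
#' s-t paths passing through v on the unweighted directed support graph
#' (ties split fractionally, endpoints excluded, self-loops ignored).
#' High values mark the catalysts that relay cascades between otherwise
#' distant perils.
#'
#' @param a A `reduced_adjacency`.
#' @return Named non-negative numeric vector (unnormalized pair counts).
#' @export
betweenness_centrality <- function(a) {
  g <- support_graph(a, self_loops = FALSE)
  igraph::betweenness(g, directed = TRUE, normalized = FALSE)
}

#' Full centrality report
#'
#' @param a A `reduced_adjacency`.
#' @param registry Optional `peril_registry` supplying system labels.
#' @param top_k Size of the per-measure top lists (default 5).
#' @param self_loops Count self-loops in degrees (default `TRUE`).
#' @return A `centrality_report`: list with `table` (data frame of id,
#'   system, in_degree, out_degree, closeness, betweenness) and `top`
#'   (named list of top-`top_k` id vectors per measure, ties broken by
#'   registry order).
#' @export
centrality_report <- function(a, registry = NULL, top_k = 5L,
                              self_loops = TRUE) {
  deg <- degree_centralities(a, self_loops = self_loops)
  tab <- data.frame(
    id = rownames(a),
    system = if (!is.null(registry)) {
      peril_system(registry, rownames(a))
    } else NA_character_,
    in_degree = as.integer(deg$in_degree),
    out_degree = as.integer(deg$out_degree),
    closeness = closeness_centrality(a),
    betweenness = betweenness_centrality(a),
    row.names = NULL
  )
  top <- lapply(c(in_degree = "in_degree", out_degree = "out_degree",
                  closeness = "closeness", betweenness = "betweenness"),
                function(col) {
                  tab$id[order(-tab[[col]])][seq_len(min(top_k, nrow(tab)))]
                })
  structure(list(table = tab, top = top, top_k = top_k),
            class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, ...) {
  cat("Centrality report (", nrow(x$table), " perils)\n", sep = "")
  for (msr in names(x$top)) {
    cat(sprintf(" top-%d %-11s: %s\n", x$top_k, msr,
                paste(x$top[[msr]], collapse = " ")))
  }
  invisible(x)
}

#' Export the interaction graph
#'
#' Writes the support graph with node attributes (id, system, centralities)
#' and edge probabilities.
#'
#' @param a A `reduced_adjacency`.
#' @param path Output file.
#' @param format `"edgelist"` (TSV from/to/probability), `"dot"`, or
#'   `"graphml"`.
#' @param registry Optional `peril_registry` for system attributes.
#' @return `path`, invisibly.
#' @export
export_graph <- function(a, path, format = c("edgelist", "dot", "graphml"),
                         registry = NULL) {
  format <- match.arg(format)
  idx <- which(unclass(a) > 0, arr.ind = TRUE)
  edges <- data.frame(from = rownames(a)[idx[, 1L]],
                      to = colnames(a)[idx[, 2L]],
                      probability = unclass(a)[idx])
  edges <- edges[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  if (format == "edgelist") {
    utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  g <- support_graph(a, self_loops = TRUE)
  rep <- centrality_report(a, registry = registry)
  igraph::V(g)$system <- rep$table$system
  igraph::V(g)$in_degree <- rep$table$in_degree
  igraph::V(g)$out_degree <- rep$table$out_degree
  igraph::V(g)$closeness <- rep$table$closeness
  igraph::V(g)$betweenness <- rep$table$betweenness
  el <- igraph::as_edgelist(g)
  igraph::E(g)$probability <- unclass(a)[cbind(el[, 1L], el[, 2L])]
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    writeLines(c(
      "digraph cascades {",
      sprintf("  \"%s\" [system=\"%s\"];", rep$table$id,
              rep$table$system),
      sprintf("  \"%s\" -> \"%s\" [probability=%g];", edges$from, edges$to,
              edges$probability),
      "}"), path)
  }
  invisible(path)
}
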