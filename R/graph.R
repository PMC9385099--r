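#' Signed pathway graph
#'
#' Constructs a directed gene-gene graph for one pathway. Edges carry
#' discrete weights in \{-1, 0, +1\} (repression / neutral / activation),
#' the convention used by curated signalling databases such as KEGG.
#'
#' @param name pathway identifier.
#' @param edges data frame (or NULL) with columns \code{from}, \code{to},
#'   \code{weight}; weights must be -1, 0 or +1.
#' @param nodes character vector of gene identifiers; defaults to the edge
#'   endpoints. Nodes not incident to any edge are kept as singletons.
#' @param bidirected optional data frame with columns \code{from}, \code{to}
#'   giving unordered gene pairs connected by a bidirected edge. Accepted in
#'   the data model but dropped (with a warning) by the fitting path.
#'
#' @return an object of class \code{pathway_graph}.
#' @export
pathway_graph <- function(name, edges = NULL, nodes = NULL, bidirected = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "weight") %in% names(edges)))
    stop("edges must have columns 'from', 'to', 'weight'")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.integer(edges$weight)
  if (nrow(edges) > 0) {
    if (!all(edges$weight %in% c(-1L, 0L, 1L)))
      stop("edge weights must be -1, 0 or +1 in pathway '", name, "'")
    if (any(edges$from == edges$to))
      stop("self-loops are not allowed in pathway '", name, "'")
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate directed edges in pathway '", name, "'")
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  if (length(nodes) == 0L) stop("pathway '", name, "' has no nodes")
  if (!is.null(bidirected)) {
    bidirected <- as.data.frame(bidirected, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(bidirected)))
      stop("bidirected must have columns 'from', 'to'")
    if (!all(c(bidirected$from, bidirected$to) %in% nodes))
      stop("bidirected edge endpoints must be pathway nodes")
  }
  structure(list(name = as.character(name), nodes = nodes, edges = edges,
                 bidirected = bidirected),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph '", x$name, "': ", length(x$nodes), " nodes, ",
      nrow(x$edges), " signed directed edges\n", sep = "")
  invisible(x)
}

#' Convert a pathway graph to an igraph object
#'
#' Singleton genes are retained as isolated vertices; the \code{weight}
#' edge attribute carries the sign.
#'
#' @param g a \code{pathway_graph}.
#' @return an \pkg{igraph} directed graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  igraph::graph_from_data_frame(g$edges, directed = TRUE, vertices = g$nodes)
}

#' Augment a pathway with an exogenous binary group node
#'
#' Adds a reserved group node X with an edge X -> j to every gene, so that
#' even pathways made of several components and singleton genes become a
#' single connected graph. Genes are partitioned into exogenous genes
#' \code{v_x} (no gene parents: sources and singletons, tested marginally)
#' and endogenous genes \code{v_y} (connectors and sinks, tested
#' conditionally on their parents).
#'
#' @param g a \code{pathway_graph}.
#' @param group_node reserved identifier for the group node.
#' @return an object of class \code{augmented_graph} with fields
#'   \code{base}, \code{group_node}, \code{v_x}, \code{v_y}.
#' @export
augment_with_group <- function(g, group_node = "GROUP") {
  stopifnot(inherits(g, "pathway_graph"))
  if (group_node %in% g$nodes)
    stop("gene '", group_node, "' clashes with the reserved group node; ",
         "choose another 'group_node'")
  has_parent <- g$nodes %in% g$edges$to
  structure(list(base = g, group_node = group_node,
                 v_x = g$nodes[!has_parent], v_y = g$nodes[has_parent]),
            class = "augmented_graph")
}

#' @export
print.augmented_graph <- function(x, ...) {
  cat("augmented_graph on '", x$base$name, "': ",
      length(x$base$nodes) + 1L, " nodes (incl. group node '", x$group_node,
      "'), ", nrow(x$base$edges) + length(x$base$nodes),
      " directed edges; |v_x| = ", length(x$v_x),
      ", |v_y| = ", length(x$v_y), "\n", sep = "")
  invisible(x)
}

#' Pathway up/down regulation from edge weights
#'
#' The total sum of the signed edge weights classifies the pathway as
#' down-regulated when the sum is less than 1 and up-regulated otherwise.
#' Pathways with no +1 or -1 edge weight get status \code{not_available}.
#'
#' @param g a \code{pathway_graph}.
#' @return list with \code{status} ("up", "down" or "not_available") and
#'   integer \code{weight_sum}.
#' @export
pathway_regulation <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  ws <- sum(g$edges$weight)
  status <- if (!any(g$edges$weight != 0L)) "not_available"
            else if (ws < 1L) "down" else "up"
  list(status = status, weight_sum = as.integer(ws))
}

#' Largest weakly connected component
#'
#' Induced subgraph on the largest weakly connected component; when several
#' components tie for the maximum size, the component containing the
#' lexicographically smallest node label is taken.
#'
#' @param g a \code{pathway_graph}.
#' @return a \code{pathway_graph} on the winning component.
#' @export
max_component <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  if (length(g$nodes) == 0L) stop("empty graph")
  comp <- igraph::components(as_igraph(g), mode = "weak")
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    # tie-break: smallest node label over the tied components
    first_label <- vapply(cand, function(k) {
      min(names(comp$membership)[comp$membership == k])
    }, character(1))
    cand <- cand[order(first_label)[1]]
  }
  keep <- names(comp$membership)[comp$membership == cand[1]]
  subgraph_on(g, keep)
}

subgraph_on <- function(g, keep) {
  e <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, , drop = FALSE]
  b <- g$bidirected
  if (!is.null(b))
    b <- b[b$from %in% keep & b$to %in% keep, , drop = FALSE]
  pathway_graph(g$name, edges = e, nodes = keep, bidirected = b)
}

#' Size and connectivity filter for pathway collections
#'
#' Keeps pathways whose node count lies in \code{[min_nodes, max_nodes]}
#' and whose largest weakly connected component covers at least
#' \code{min_component_frac} of the nodes; survivors are reduced to their
#' largest component.
#'
#' @param gs list of \code{pathway_graph}.
#' @param min_nodes,max_nodes node-count bounds (defaults 30 and 300).
#' @param min_component_frac minimum fraction of nodes in the largest
#'   component (default 0.6).
#' @return list of \code{pathway_graph} (largest components of survivors).
#' @export
filter_pathways <- function(gs, min_nodes = 30, max_nodes = 300,
                            min_component_frac = 0.6) {
  out <- list()
  for (g in gs) {
    n <- length(g$nodes)
    if (n < min_nodes || n > max_nodes) next
    mc <- max_component(g)
    if (length(mc$nodes) / n < min_component_frac) next
    out[[length(out) + 1L]] <- mc
  }
  out
}
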