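#' Read pathway graphs from disk
#'
#' Supported dialects: GraphML and GML (via \pkg{igraph}, expecting an edge
#' attribute named \code{weight}) and a plain signed edge list. The edge
#' list is whitespace- or tab-separated with columns \code{source},
#' \code{target}, \code{weight} (a header line is optional) and may carry
#' singleton genes on a comment line \code{# nodes: g1 g2 ...}. One file
#' yields one pathway; the pathway name is the file name without extension.
#'
#' Edges with a missing weight get weight 0 with a warning; a weight outside
#' \{-1, 0, +1\} is an error naming the file.
#'
#' @param path a file, a vector of files, or a directory (all regular files
#'   inside are read).
#' @param format one of "graphml", "gml", "signed_edge_list".
#' @return list of \code{pathway_graph}.
#' @export
read_pathways <- function(path,
                          format = c("signed_edge_list", "graphml", "gml")) {
  format <- match.arg(format)
  files <- path
  if (length(path) == 1L && dir.exists(path))
    files <- sort(list.files(path, full.names = TRUE))
  lapply(files, function(f) {
    name <- sub("\\.[^.]*$", "", basename(f))
    g <- tryCatch({
      if (format == "signed_edge_list") read_signed_edge_list(f, name)
      else read_igraph_file(f, format, name)
    }, error = function(e) {
      stop("failed to read pathway file '", f, "': ", conditionMessage(e),
           call. = FALSE)
    })
    g
  })
}

read_igraph_file <- function(f, format, name) {
  ig <- igraph::read_graph(f, format = format)
  ed <- igraph::as_data_frame(ig, what = "edges")
  if (nrow(ed) > 0 && !"weight" %in% names(ed)) {
    warning("no 'weight' edge attribute in '", f, "'; assuming 0")
    ed$weight <- 0L
  }
  if (nrow(ed) > 0 && anyNA(ed$weight)) {
    warning("missing edge weights in '", f, "'; set to 0")
    ed$weight[is.na(ed$weight)] <- 0L
  }
  if (nrow(ed) > 0 && !all(ed$weight %in% c(-1, 0, 1)))
    stop("edge weight outside {-1, 0, +1}")
  nodes <- igraph::V(ig)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(ig)))
  pathway_graph(name,
                edges = ed[, intersect(c("from", "to", "weight"), names(ed)),
                           drop = FALSE],
                nodes = nodes)
}

read_signed_edge_list <- function(f, name) {
  lines <- readLines(f)
  extra_nodes <- character()
  node_lines <- grep("^#\\s*nodes:", lines)
  for (i in node_lines) {
    extra_nodes <- c(extra_nodes,
                     strsplit(trimws(sub("^#\\s*nodes:", "", lines[i])),
                              "\\s+")[[1]])
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L)
    return(pathway_graph(name, nodes = extra_nodes))
  toks <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(toks) < 2L | lengths(toks) > 3L)
  if (length(bad))
    stop("malformed edge line ", bad[1])
  # optional header line
  if (tolower(toks[[1]][1]) == "source") toks <- toks[-1]
  ed <- data.frame(
    from = vapply(toks, `[`, "", 1L),
    to = vapply(toks, `[`, "", 2L),
    weight = vapply(toks, function(t) {
      if (length(t) < 3L || t[3] == "" || toupper(t[3]) == "NA") NA_character_
      else t[3]
    }, ""),
    stringsAsFactors = FALSE)
  if (anyNA(ed$weight)) {
    warning("missing edge weights in '", f, "'; set to 0")
    ed$weight[is.na(ed$weight)] <- "0"
  }
  w <- suppressWarnings(as.numeric(ed$weight))
  if (anyNA(w) || !all(w %in% c(-1, 0, 1)))
    stop("edge weight outside {-1, 0, +1}")
  ed$weight <- as.integer(w)
  pathway_graph(name, edges = ed, nodes = extra_nodes)
}

#' Write a pathway graph as a signed edge list
#'
#' Inverse of \code{\link{read_pathways}} for the
#' \code{signed_edge_list} dialect: a \code{# nodes:} comment preserves
#' singleton genes, then a header and one tab-separated edge per line.
#'
#' @param g a \code{pathway_graph}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pathway <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# nodes:", paste(g$nodes, collapse = " ")), con)
  writeLines("source\ttarget\tweight", con)
  if (nrow(g$edges) > 0)
    writeLines(paste(g$edges$from, g$edges$to, g$edges$weight, sep = "\t"),
               con)
  invisible(path)
}
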