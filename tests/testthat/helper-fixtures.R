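# Shared fixture builders; everything is generated in code.

chain_graph <- function(nodes = c("A", "B", "C"), weights = NULL) {
  k <- length(nodes)
  if (is.null(weights)) weights <- rep(1L, k - 1)
  pathway_graph("chain",
                edges = data.frame(from = nodes[-k], to = nodes[-1],
                                   weight = weights))
}

star_graph <- function(center = "H", leaves = paste0("L", 1:4)) {
  pathway_graph("star",
                edges = data.frame(from = center, to = leaves, weight = 1L))
}

# Random signed DAG for property-style tests.
random_dag <- function(n_nodes, p_edge = 0.2, name = "rand") {
  labels <- sprintf("n%02d", seq_len(n_nodes))
  ord <- sample(labels)
  from <- character(0); to <- character(0)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < p_edge) {
        from <- c(from, ord[i]); to <- c(to, ord[j])
      }
    }
  }
  ed <- if (length(from))
    data.frame(from = from, to = to,
               weight = sample(c(-1L, 1L), length(from), replace = TRUE))
  else NULL
  pathway_graph(name, edges = ed, nodes = labels)
}

# Noise dataset (no group structure) for the given genes.
noise_data <- function(genes, n1 = 15, n0 = 15) {
  X <- matrix(stats::rnorm((n1 + n0) * length(genes)), n1 + n0,
              dimnames = list(NULL, genes))
  expression_dataset(X, c(rep(1L, n1), rep(0L, n0)))
}

quiet_semgsa <- function(...) suppressMessages(suppressWarnings(semgsa(...)))
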