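#' Generate a collection of synthetic signed pathway graphs
#'
#' Each pathway is a random connected directed acyclic graph: a random
#' oriented spanning tree (guaranteeing weak connectivity) plus extra
#' forward edges. Edge signs are +1 with probability \code{p_activation}
#' and -1 otherwise, mimicking the predominance of activating interactions
#' in curated signalling databases. Node labels are drawn without
#' replacement (per pathway) from a shared gene universe, so pathways
#' overlap moderately, as KEGG pathways do.
#'
#' @param n_pathways number of graphs (default 20).
#' @param size_range inclusive node-count range (default c(30, 60)).
#' @param universe gene identifiers to draw node labels from; by default a
#'   universe of 3 * n_pathways * mean(size_range) synthetic gene names,
#'   giving the sparse inter-pathway overlap typical of curated
#'   collections (a few shared genes per pathway pair).
#' @param extra_edge_frac extra (non-tree) forward edges as a fraction of
#'   the node count (default 0.4).
#' @param p_activation probability that an edge weight is +1 (default 0.75).
#' @param seed optional integer seed.
#' @return list of \code{pathway_graph}.
#' @export
simulate_pathways <- function(n_pathways = 20, size_range = c(30, 60),
                              universe = NULL, extra_edge_frac = 0.4,
                              p_activation = 0.75, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(universe)) {
    m <- ceiling(3 * n_pathways * mean(size_range))
    universe <- sprintf("g%04d", seq_len(m))
  }
  lapply(seq_len(n_pathways), function(i) {
    nn <- sample(seq(size_range[1], size_range[2]), 1)
    labels <- sample(universe, nn)
    # oriented spanning tree over a random topological order
    ord <- sample(labels)
    efrom <- ord[vapply(2:nn, function(j) sample.int(j - 1L, 1L), 1L)]
    eto <- ord[2:nn]
    n_extra <- round(extra_edge_frac * nn)
    if (n_extra > 0) {
      a <- sample.int(nn, n_extra, replace = TRUE)
      b <- sample.int(nn, n_extra, replace = TRUE)
      lo <- pmin(a, b); hi <- pmax(a, b)
      ok <- lo < hi
      efrom <- c(efrom, ord[lo[ok]]); eto <- c(eto, ord[hi[ok]])
    }
    ed <- unique(data.frame(from = efrom, to = eto,
                            stringsAsFactors = FALSE))
    ed$weight <- ifelse(stats::runif(nrow(ed)) < p_activation, 1L, -1L)
    pathway_graph(sprintf("path%02d", i), edges = ed, nodes = labels)
  })
}

#' Affected-gene selection by betweenness
#'
#' The \code{s} nodes with the highest directed, unweighted shortest-path
#' betweenness; ties broken by node label order.
#'
#' @param g a \code{pathway_graph}.
#' @param s number of genes to select.
#' @return character vector of gene identifiers.
#' @export
select_affected_betweenness <- function(g, s) {
  if (length(g$nodes) < s) {
    warning("pathway '", g$name, "' has fewer than s nodes; taking all")
    return(g$nodes)
  }
  btw <- igraph::betweenness(as_igraph(g), directed = TRUE, weights = NA)
  nm <- names(btw)
  nm[order(-btw, nm)][seq_len(s)]
}

#' Affected-gene selection by community membership
#'
#' Greedy modularity maximization on the undirected skeleton; \code{s}
#' genes are sampled uniformly without replacement from the largest
#' community (ties broken by smallest member label).
#'
#' @param g a \code{pathway_graph}.
#' @param s number of genes to sample.
#' @param seed optional integer seed for the sampling step.
#' @return character vector of gene identifiers.
#' @export
select_affected_community <- function(g, s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  skel <- igraph::as_undirected(as_igraph(g), mode = "collapse",
                                edge.attr.comb = "ignore")
  comm <- igraph::membership(igraph::cluster_fast_greedy(skel))
  groups <- split(names(comm), as.integer(comm))
  sizes <- lengths(groups)
  cand <- groups[sizes == max(sizes)]
  first <- vapply(cand, min, character(1))
  pool <- cand[[order(first)[1]]]
  if (length(pool) < s) {
    warning("largest community in '", g$name,
            "' has fewer than s members; taking the whole community")
    return(sort(pool))
  }
  sample(pool, s)
}

#' Affected-gene selection by neighbourhood size
#'
#' For every vertex the order-\code{order} neighbourhood on the undirected
#' skeleton (vertices within that distance, centre included) is computed;
#' \code{s} genes are sampled from the largest neighbourhood (size ties
#' broken by centre label order).
#'
#' @param g a \code{pathway_graph}.
#' @param s number of genes to sample.
#' @param order neighbourhood order (default 2).
#' @param seed optional integer seed for the sampling step.
#' @return character vector of gene identifiers.
#' @export
select_affected_neighbourhood <- function(g, s, order = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ig <- as_igraph(g)
  hoods <- igraph::ego(ig, order = order, mode = "all")
  sizes <- lengths(hoods)
  centers <- g$nodes[order(-sizes, g$nodes)]
  best <- centers[1]
  pool <- names(hoods[[match(best, g$nodes)]])
  if (length(pool) < s) {
    warning("largest order-", order, " neighbourhood in '", g$name,
            "' has fewer than s members; taking it whole")
    return(sort(pool))
  }
  sample(pool, s)
}

# Up/down sign of an affected gene: sign of its summed outgoing edge
# weights in the pathway; genes with sum 0 (or no outgoing edge) get +1.
gene_signs <- function(g, genes) {
  ws <- vapply(genes, function(gn) {
    sum(g$edges$weight[g$edges$from == gn])
  }, numeric(1))
  ifelse(ws < 0, -1L, 1L)
}

#' Build a dysregulation design over a pathway collection
#'
#' Selects \code{s} affected genes in each designated pathway by the chosen
#' topology rule, assigns each its up/down sign from the pathway's edge
#' weights, deduplicates the union (first occurrence keeps its sign), and
#' identifies the true-negative pathways: non-designated pathways
#' containing at most one affected gene.
#'
#' @param gs list of \code{pathway_graph}.
#' @param q1_names names of the pathways to dysregulate.
#' @param topology "betweenness", "community" or "neighbourhood".
#' @param s affected genes per pathway (default 10).
#' @param seed optional integer seed (used by the sampling topologies).
#' @return list with \code{affected} (data frame gene/sign, the unique
#'   union), \code{per_pathway} (named list of gene vectors) and
#'   \code{q0_names}.
#' @export
build_design <- function(gs, q1_names,
                         topology = c("betweenness", "community",
                                      "neighbourhood"),
                         s = 10, seed = NULL) {
  topology <- match.arg(topology)
  names(gs) <- vapply(gs, function(g) g$name, character(1))
  if (!all(q1_names %in% names(gs)))
    stop("unknown q1 pathway name(s): ",
         paste(setdiff(q1_names, names(gs)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  per <- list(); genes <- character(0); signs <- integer(0)
  for (nm in q1_names) {
    g <- gs[[nm]]
    sel <- switch(topology,
                  betweenness = select_affected_betweenness(g, s),
                  community = select_affected_community(g, s),
                  neighbourhood = select_affected_neighbourhood(g, s))
    per[[nm]] <- sel
    new <- !sel %in% genes
    genes <- c(genes, sel[new])
    signs <- c(signs, gene_signs(g, sel[new]))
  }
  affected <- data.frame(gene = genes, sign = signs,
                         stringsAsFactors = FALSE)
  q0 <- setdiff(names(gs), q1_names)
  hits <- vapply(gs[q0], function(g) sum(g$nodes %in% genes), integer(1))
  list(affected = affected, per_pathway = per,
       q0_names = q0[hits <= 1L])
}

#' Generate standardized multivariate-normal expression data
#'
#' Draws subjects-by-genes data from a zero-mean multivariate normal with
#' either independent genes or a block correlation structure (within-block
#' correlation \code{rho}), then standardizes each gene to mean 0 and
#' variance 1 within each group, emulating the per-group normalization
#' applied to real expression matrices before signal injection.
#'
#' @param genes gene identifiers (columns).
#' @param n_cases,n_controls group sizes (defaults 46 and 23).
#' @param corr "independent" or "block".
#' @param rho within-block correlation for \code{corr = "block"}
#'   (default 0.2).
#' @param blocks named integer/character vector mapping gene to block id;
#'   genes without a block are independent. Required for "block".
#' @param standardize per-gene per-group standardization (default TRUE, the
#'   dysregulation-harness convention: it zeroes every raw group difference
#'   so the injected shift is the only group signal). Set FALSE for raw
#'   noise, e.g. when checking null calibration of the test itself.
#' @param seed optional integer seed.
#' @return an \code{expression_dataset}; cases (group 1) come first.
#' @export
generate_base_data <- function(genes, n_cases = 46, n_controls = 23,
                               corr = c("independent", "block"), rho = 0.2,
                               blocks = NULL, standardize = TRUE,
                               seed = NULL) {
  corr <- match.arg(corr)
  if (!is.null(seed)) set.seed(seed)
  n <- n_cases + n_controls
  p <- length(genes)
  X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, genes))
  if (corr == "block") {
    if (is.null(blocks)) stop("blocks required for corr = 'block'")
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
    bl <- blocks[genes]
    for (b in unique(bl[!is.na(bl)])) {
      idx <- which(!is.na(bl) & bl == b)
      if (length(idx) < 2L) next
      z <- stats::rnorm(n)
      X[, idx] <- sqrt(rho) * z + sqrt(1 - rho) * X[, idx]
    }
  }
  group <- c(rep(1L, n_cases), rep(0L, n_controls))
  rownames(X) <- paste0(ifelse(group == 1L, "case", "ctrl"),
                        c(seq_len(n_cases), seq_len(n_controls)))
  if (standardize) {
    for (lev in c(0L, 1L)) {
      rows <- group == lev
      X[rows, ] <- scale(X[rows, , drop = FALSE])
    }
  }
  expression_dataset(X, group)
}

#' Inject a group mean shift into affected genes
#'
#' Adds \code{sign * signal} to the case subjects of every affected gene;
#' controls and unaffected genes are untouched. The signal is in units of
#' the (unit) per-gene standard deviation.
#'
#' @param data a standardized \code{expression_dataset}.
#' @param affected data frame with columns \code{gene}, \code{sign}.
#' @param signal mean shift magnitude.
#' @return the modified \code{expression_dataset}.
#' @export
inject_signal <- function(data, affected, signal) {
  stopifnot(inherits(data, "expression_dataset"))
  miss <- setdiff(affected$gene, colnames(data$matrix))
  if (length(miss))
    stop("affected gene(s) absent from the data: ",
         paste(utils::head(miss, 5), collapse = ", "))
  cases <- data$group == 1L
  for (i in seq_len(nrow(affected))) {
    data$matrix[cases, affected$gene[i]] <-
      data$matrix[cases, affected$gene[i]] + affected$sign[i] * signal
  }
  data
}

#' Simulation design for type-I-error / power evaluation
#'
#' @param topology gene-selection rule: "betweenness", "community" or
#'   "neighbourhood".
#' @param signal mean shift in per-gene standard deviations (study levels:
#'   0.5, 0.6, 0.7).
#' @param s affected genes per dysregulated pathway (default 10).
#' @param q1_pathways names of the pathways to dysregulate.
#' @param n_replicates simulation replicates (default 100).
#' @param n_rep permutations per fit (default 200 at desk scale).
#' @param n_cases,n_controls group sizes (defaults 46 and 23).
#' @param corr,rho base-data correlation structure (defaults "block", 0.2).
#' @param seed integer seed; every source of randomness in
#'   \code{\link{run_simulation}} descends from it.
#' @return object of class \code{simulation_design}.
#' @export
simulation_design <- function(topology = "betweenness", signal = 0.5,
                              s = 10, q1_pathways, n_replicates = 100,
                              n_rep = 200, n_cases = 46, n_controls = 23,
                              corr = "block", rho = 0.2, seed = 1) {
  stopifnot(signal > 0, s >= 1, length(q1_pathways) >= 1)
  structure(list(topology = match.arg(topology, c("betweenness", "community",
                                                  "neighbourhood")),
                 signal = signal, s = s, q1_pathways = q1_pathways,
                 n_replicates = as.integer(n_replicates),
                 n_rep = as.integer(n_rep), n_cases = n_cases,
                 n_controls = n_controls, corr = corr, rho = rho,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Co-expression block map over a pathway collection
#'
#' Builds the block assignment used by \code{\link{generate_base_data}}:
#' the genes of each pathway are split into co-expression modules of about
#' \code{module_size} genes (a gene keeps the module of the first pathway
#' containing it). Correlating modules rather than whole pathways mirrors
#' real expression data, where co-expression is modular and the average
#' pairwise correlation across a whole pathway is small.
#'
#' @param gs list of \code{pathway_graph}.
#' @param module_size target module size (default 10).
#' @return named character vector mapping gene to block identifier.
#' @export
coexpression_blocks <- function(gs, module_size = 10) {
  blocks <- character(0)
  for (g in gs) {
    new <- setdiff(g$nodes, names(blocks))
    if (!length(new)) next
    k <- max(1L, round(length(new) / module_size))
    blocks[new] <- paste0(g$name, ".m",
                          rep(seq_len(k), length.out = length(new),
                              each = ceiling(length(new) / k))[
                                seq_along(new)])
  }
  blocks
}

#' Run the dysregulation simulation
#'
#' Per replicate: draw the affected set (the sampling topologies resample
#' each replicate, so the true-negative set can vary), generate fresh
#' standardized base data, inject the signed mean shift into the case
#' group, run \code{\link{semgsa}} on all pathways, and record which
#' pathways have \code{PVAL < rejection_alpha}. Type I error is the
#' rejection fraction over true-negative (q0) pathways and power the
#' rejection fraction over dysregulated (q1) pathways, averaged over
#' replicates.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param pathways list of \code{pathway_graph} (the full collection).
#' @param rejection_alpha pathway rejection threshold on PVAL
#'   (default 0.05).
#' @return object of class \code{sim_metrics}: \code{type_i_error},
#'   \code{power}, their Monte-Carlo standard errors (sd of per-replicate
#'   fractions / sqrt(replicates)), and the per-replicate table.
#' @export
run_simulation <- function(design, pathways, rejection_alpha = 0.05) {
  stopifnot(inherits(design, "simulation_design"))
  names(pathways) <- vapply(pathways, function(g) g$name, character(1))
  all_genes <- sort(unique(unlist(lapply(pathways, function(g) g$nodes))))
  blocks <- coexpression_blocks(pathways)
  set.seed(design$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, design$n_replicates)
  per_rep <- vector("list", design$n_replicates)
  for (r in seq_len(design$n_replicates)) {
    set.seed(sub_seeds[r])
    des <- build_design(pathways, design$q1_pathways, design$topology,
                        s = design$s)
    data <- generate_base_data(all_genes, design$n_cases, design$n_controls,
                               corr = design$corr, rho = design$rho,
                               blocks = blocks)
    data <- inject_signal(data, des$affected, design$signal)
    fit <- suppressMessages(
      semgsa(pathways, data, n_rep = design$n_rep))
    rej <- fit$gsa$PVAL < rejection_alpha
    names(rej) <- fit$gsa$pathway
    per_rep[[r]] <- data.frame(
      replicate = r,
      t1 = if (length(des$q0_names)) mean(rej[des$q0_names]) else NA_real_,
      power = mean(rej[design$q1_pathways]),
      n_q0 = length(des$q0_names),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, per_rep)
  structure(list(
    type_i_error = mean(tab$t1, na.rm = TRUE), power = mean(tab$power),
    t1_mc_se = stats::sd(tab$t1, na.rm = TRUE) /
      sqrt(sum(!is.na(tab$t1))),
    power_mc_se = stats::sd(tab$power) / sqrt(nrow(tab)),
    replicates = tab, design = design),
    class = "sim_metrics")
}

#' @export
print.sim_metrics <- function(x, ...) {
  cat("dysregulation simulation (", x$design$topology, ", signal ",
      x$design$signal, ", ", nrow(x$replicates), " replicates)\n",
      "  type I error: ", signif(x$type_i_error, 4),
      " (MC se ", signif(x$t1_mc_se, 3), ")\n",
      "  power:        ", signif(x$power, 4),
      " (MC se ", signif(x$power_mc_se, 3), ")\n", sep = "")
  invisible(x)
}
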