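#' One-sided p-value for node activation or inhibition
#'
#' Converts a two-sided node p-value and the sign of the group path into a
#' one-sided p-value: for the activation alternative, \eqn{p/2} when
#' \eqn{\beta > 0} and \eqn{1 - p/2} when \eqn{\beta < 0}; the inhibition
#' alternative mirrors this. A zero effect gives 0.5 in both directions.
#'
#' @param p two-sided p-value(s) in (0, 1].
#' @param beta signed group-effect estimate(s).
#' @param direction "activation" or "inhibition".
#' @return one-sided p-value(s).
#' @export
one_sided <- function(p, beta, direction = c("activation", "inhibition")) {
  direction <- match.arg(direction)
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  act <- ifelse(beta > 0, p / 2, ifelse(beta < 0, 1 - p / 2, 0.5))
  inh <- ifelse(beta > 0, 1 - p / 2, ifelse(beta < 0, p / 2, 0.5))
  if (direction == "activation") act else inh
}

#' Brown's method for combining dependent one-sided p-values
#'
#' Computes \eqn{X^2 = -2 \sum_j \log p_j} and refers \eqn{X^2 / c} to a
#' chi-square distribution with \eqn{f} degrees of freedom, where the scale
#' \eqn{c} and effective degrees of freedom \eqn{f} are matched to the first
#' two moments of \eqn{X^2} under dependence. The covariance between
#' \eqn{-2\log p_i} and \eqn{-2\log p_j} is approximated from the pairwise
#' correlation \eqn{\rho_{ij}} of the underlying gene statistics by the
#' polynomial \eqn{3.263\rho + 0.710\rho^2 + 0.027\rho^3} (Kost &
#' McDermott). With zero correlation this reduces exactly to Fisher's
#' method (\eqn{c = 1}, \eqn{f = 2k}).
#'
#' @param p_one_sided vector of one-sided p-values in (0, 1].
#' @param gene_corr correlation matrix of the underlying gene statistics
#'   (dimension = number of p-values); NULL means independence.
#' @return list with \code{x2}, \code{c}, \code{f}, \code{p_combined}.
#' @export
brown_combine <- function(p_one_sided, gene_corr = NULL) {
  k <- length(p_one_sided)
  if (k == 0L) stop("no p-values to combine")
  if (any(p_one_sided <= 0 | p_one_sided > 1)) stop("p must lie in (0, 1]")
  x2 <- -2 * sum(log(p_one_sided))
  e <- 2 * k
  v <- 4 * k
  if (!is.null(gene_corr) && k > 1L) {
    gene_corr <- as.matrix(gene_corr)
    if (!all(dim(gene_corr) == k))
      stop("gene_corr dimension does not match the number of p-values")
    rho <- gene_corr[upper.tri(gene_corr)]
    rho <- pmin(pmax(rho, -1), 1)
    v <- v + 2 * sum(3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3)
  }
  v <- max(v, 1e-12)
  cc <- v / (2 * e)
  f <- 2 * e^2 / v
  p_comb <- stats::pchisq(x2 / cc, df = f, lower.tail = FALSE)
  list(x2 = x2, c = cc, f = f,
       p_combined = min(max(p_comb, 1e-300), 1))
}

#' Global pathway perturbation p-value
#'
#' Bonferroni combination of the activation and inhibition scores:
#' \eqn{PVAL = \min(1, 2 \min(pNA, pNI))}.
#'
#' @param pNA,pNI Brown-combined activation / inhibition p-values.
#' @return the pathway p-value.
#' @export
pathway_pval <- function(pNA, pNI) {
  if (any(c(pNA, pNI) <= 0 | c(pNA, pNI) > 1)) stop("p must lie in (0, 1]")
  pmin(1, 2 * pmin(pNA, pNI))
}

#' Bonferroni adjustment across pathways
#'
#' \eqn{ADJP = \min(K \times PVAL, 1)} with \eqn{K} the number of input
#' pathways.
#'
#' @param pvals pathway p-values.
#' @param K number of input pathways (defaults to \code{length(pvals)}).
#' @return adjusted p-values.
#' @export
adjust_global <- function(pvals, K = length(pvals)) {
  pmin(K * pvals, 1)
}

#' Select differentially expressed genes within a pathway
#'
#' Adjusts the node p-values within the pathway with the chosen
#' multiple-testing method and returns the genes whose adjusted p-value
#' falls below \code{alpha}.
#'
#' @param fits a \code{node_fits} data frame with \code{p_two_sided} filled.
#' @param method one of "BH", "bonferroni", "holm" (default "BH").
#' @param alpha significance level (default 0.05).
#' @return character vector of DEG identifiers.
#' @export
select_degs <- function(fits, method = "BH", alpha = 0.05) {
  supported <- c("BH", "bonferroni", "holm")
  if (!method %in% supported)
    stop("unknown method '", method, "'; supported: ",
         paste(supported, collapse = ", "))
  if (anyNA(fits$p_two_sided)) stop("node p-values are missing")
  adj <- stats::p.adjust(fits$p_two_sided, method = method)
  fits$gene[adj < alpha]
}

#' Overall pathway perturbation label
#'
#' Combines the edge-weight regulation call (up/down) with the node
#' perturbation direction (activated when the activation score beats the
#' inhibition score, inhibited otherwise): up + activated = "up act",
#' down + activated = "down inh", up + inhibited = "down act",
#' down + inhibited = "up inh". Pathways without a +1 or -1 edge weight
#' get "NA".
#'
#' @param reg a regulation call from \code{\link{pathway_regulation}}.
#' @param pNA,pNI Brown activation / inhibition p-values.
#' @return one of "up act", "up inh", "down act", "down inh", "NA".
#' @export
perturbation_status <- function(reg, pNA, pNI) {
  if (reg$status == "not_available") return("NA")
  if (pNA == pNI)
    warning("activation and inhibition scores tie exactly; ",
            "treating the node perturbation as activated")
  activated <- pNA <= pNI
  if (reg$status == "up") {
    if (activated) "up act" else "down act"
  } else {
    if (activated) "down inh" else "up inh"
  }
}

#' Absolute and percentile pathway ranks
#'
#' Pathways sharing a p-value share a (dense) rank; the percentile rank is
#' the dense rank divided by the number of unique p-values, times 100.
#'
#' @param pvals pathway p-values.
#' @return list with \code{rank} and \code{percentile}.
#' @export
rank_pathways <- function(pvals) {
  u <- sort(unique(pvals))
  r <- match(pvals, u)
  list(rank = r, percentile = r / length(u) * 100)
}

# Pairwise gene correlation feeding Brown's correction: James-Stein shrunk
# Pearson correlation of the pathway genes pooled across groups after
# per-group centering, so a group mean shift does not masquerade as
# co-expression and sampling noise in the correlations does not inflate
# the dependence correction.
pooled_correlation <- function(data, genes) {
  Y <- data$matrix[, genes, drop = FALSE]
  for (lev in c(0L, 1L)) {
    rows <- data$group == lev
    Y[rows, ] <- scale(Y[rows, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  sds <- apply(Y, 2, stats::sd)
  C <- diag(length(genes))
  dimnames(C) <- list(genes, genes)
  ok <- sds > 0  # degenerate genes carry no correlation information
  if (sum(ok) > 1)
    C[ok, ok] <- stats::cor(Y[, ok, drop = FALSE])
  lambda <- shrinkage_intensity(C, nrow(Y))
  C <- (1 - lambda) * C
  diag(C) <- 1
  C
}

#' Topology-based gene set analysis with a group-augmented SEM
#'
#' For each pathway: classify up/down regulation from the signed edge
#' weights, add the exogenous binary group node, estimate node-wise group
#' paths by least squares under the common-effect linear SEM, derive
#' two-sided node p-values from a label-permutation null via the normal
#' moment approximation, convert them to one-sided activation and
#' inhibition p-values, combine each direction across the pathway with
#' Brown's method (correcting for gene co-expression), and summarise the
#' pathway with \code{PVAL = min(1, 2 min(pNA, pNI))}, a Bonferroni
#' adjustment \code{ADJP = min(K PVAL, 1)} across the K input pathways,
#' a perturbation label, and the list of differentially expressed genes.
#'
#' Genes present in a graph but absent from the data are dropped from that
#' graph (a message reports the count); pathways left with fewer than two
#' genes are skipped with a warning.
#'
#' @param g a \code{pathway_graph} or list of them.
#' @param data an \code{expression_dataset}, or a subjects-by-genes matrix
#'   if \code{group} is supplied.
#' @param group binary labels (1 = case, 0 = control) when \code{data} is a
#'   plain matrix.
#' @param method multiple-testing correction for DEG selection
#'   (default "BH").
#' @param alpha significance level for DEG selection (default 0.05).
#' @param n_rep number of label permutations (default 1000).
#' @param seed optional integer seed; all permutations are drawn from the
#'   single RNG stream it initializes, pathway by pathway in input order.
#' @param shrink_if_not_pd regularize non-positive-definite pathway gene
#'   covariances (default TRUE).
#' @param group_node reserved group-node identifier (default "GROUP").
#' @return an object of class \code{semgsa}: list with \code{gsa} (data
#'   frame with columns pathway, No.nodes, No.DEGs, pert, pNA, pNI, PVAL,
#'   ADJP, ordered by ascending PVAL), \code{DEG} (named list of DEG
#'   vectors), \code{fits} (named list of \code{node_fits}), and the call
#'   configuration.
#' @export
semgsa <- function(g, data, group = NULL, method = "BH", alpha = 0.05,
                   n_rep = 1000, seed = NULL, shrink_if_not_pd = TRUE,
                   group_node = "GROUP") {
  if (inherits(g, "pathway_graph")) g <- list(g)
  if (!length(g)) stop("no pathways supplied")
  if (!all(vapply(g, inherits, TRUE, "pathway_graph")))
    stop("g must be a pathway_graph or a list of them")
  if (!inherits(data, "expression_dataset")) {
    if (is.null(group))
      stop("supply 'group' when 'data' is not an expression_dataset")
    data <- expression_dataset(data, group)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  K <- length(g)
  if (!is.null(seed)) set.seed(seed)

  rows <- list(); degs <- list(); fit_list <- list()
  for (pg in g) {
    present <- intersect(pg$nodes, colnames(data$matrix))
    dropped <- length(pg$nodes) - length(present)
    if (dropped > 0)
      message("pathway '", pg$name, "': dropped ", dropped,
              " gene(s) absent from the data")
    if (length(present) < 2L) {
      warning("pathway '", pg$name,
              "' has fewer than 2 genes in the data; skipped")
      next
    }
    pg2 <- if (dropped > 0) subgraph_on(pg, present) else pg
    reg <- pathway_regulation(pg2)
    ag <- augment_with_group(pg2, group_node = group_node)
    eng <- pathway_engine(ag, data, n_rep = n_rep,
                          shrink_if_not_pd = shrink_if_not_pd)
    fits <- data.frame(gene = eng$genes, beta_hat = eng$beta_hat,
                       null_mean = eng$null_mean, null_sd = eng$null_sd,
                       p_two_sided = NA_real_, stringsAsFactors = FALSE)
    attr(fits, "parent_betas") <- eng$parent_betas
    class(fits) <- c("node_fits", "data.frame")
    fits <- node_pvalues(fits, fits[, c("gene", "null_mean", "null_sd")])
    C <- pooled_correlation(data, fits$gene)
    pna <- brown_combine(one_sided(fits$p_two_sided, fits$beta_hat,
                                   "activation"), C)$p_combined
    pni <- brown_combine(one_sided(fits$p_two_sided, fits$beta_hat,
                                   "inhibition"), C)$p_combined
    pval <- pathway_pval(pna, pni)
    dg <- select_degs(fits, method = method, alpha = alpha)
    rows[[pg2$name]] <- data.frame(
      pathway = pg2$name, No.nodes = length(fits$gene),
      No.DEGs = length(dg), pert = perturbation_status(reg, pna, pni),
      pNA = pna, pNI = pni, PVAL = pval, ADJP = NA_real_,
      stringsAsFactors = FALSE)
    degs[[pg2$name]] <- dg
    fit_list[[pg2$name]] <- fits
  }
  if (!length(rows)) stop("no pathway could be analysed")
  gsa <- do.call(rbind, rows)
  gsa$ADJP <- adjust_global(gsa$PVAL, K = K)
  ord <- order(gsa$PVAL, gsa$pathway)
  gsa <- gsa[ord, , drop = FALSE]
  rownames(gsa) <- NULL
  structure(list(gsa = gsa, DEG = degs[gsa$pathway],
                 fits = fit_list[gsa$pathway],
                 K = K, method = method, alpha = alpha, n_rep = n_rep,
                 seed = seed, call = match.call()),
            class = "semgsa")
}
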