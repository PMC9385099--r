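#' Fitting configuration
#'
#' @param n_rep number of group-label permutations used for the null
#'   distribution of the group paths (default 1000). Values below 100 give
#'   coarse moment estimates and trigger a warning.
#' @param seed optional integer seed for the permutation stream.
#' @param shrink_if_not_pd regularize the pathway gene covariance by
#'   James-Stein-type shrinkage when it is not positive definite
#'   (default TRUE).
#' @return object of class \code{fit_config}.
#' @export
fit_config <- function(n_rep = 1000, seed = NULL, shrink_if_not_pd = TRUE) {
  n_rep <- as.integer(n_rep)
  if (is.na(n_rep) || n_rep < 1L) stop("n_rep must be a positive integer")
  if (n_rep < 100L)
    warning("n_rep < 100: permutation null moments will be unstable")
  structure(list(n_rep = n_rep, seed = seed,
                 shrink_if_not_pd = isTRUE(shrink_if_not_pd)),
            class = "fit_config")
}

#' James-Stein-type covariance shrinkage toward a diagonal target
#'
#' If \code{S} is already positive definite (smallest eigenvalue above
#' \code{tol}) it is returned unchanged. Otherwise the correlation matrix is
#' shrunk toward the identity, \eqn{R* = (1-\lambda) R + \lambda I}, with the
#' analytic intensity of Schafer-Strimmer estimated from the normal-theory
#' variance approximation \eqn{var(r) \approx (1-r^2)^2/(n-1)}, floored so
#' the result is positive definite, and rescaled to a covariance matrix.
#'
#' @param S symmetric covariance matrix.
#' @param n sample count the covariance was estimated from.
#' @param tol positive-definiteness tolerance on the smallest eigenvalue.
#' @return a symmetric positive-definite matrix; attribute
#'   \code{"lambda"} carries the shrinkage intensity used (0 if untouched).
#' @export
shrink_covariance <- function(S, n, tol = 1e-8) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) ||
      max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be a symmetric matrix")
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > tol) {
    attr(S, "lambda") <- 0
    return(S)
  }
  d <- diag(S)
  if (any(d <= 0))
    stop("zero-variance variable(s): ",
         paste(utils::head(colnames(S)[d <= 0], 5), collapse = ", "))
  R <- stats::cov2cor(S)
  lambda <- shrinkage_intensity(R, n)
  # floor lambda so the shrunk correlation is numerically PD
  e_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (e_min <= tol && e_min < 1) {
    lambda_pd <- (2 * tol - e_min) / (1 - e_min)
    lambda <- max(lambda, min(1, lambda_pd))
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  out <- Rs * tcrossprod(sqrt(d))
  attr(out, "lambda") <- lambda
  out
}

# Schafer-Strimmer analytic shrinkage intensity toward the identity for a
# correlation matrix estimated from n samples; normal-theory approximation
# var(r) ~ (1 - r^2)^2 / (n - 1).
shrinkage_intensity <- function(R, n) {
  r2 <- R[upper.tri(R)]^2
  denom <- sum(r2)
  if (denom <= 0) return(1)
  min(1, sum((1 - r2)^2 / (n - 1)) / denom)
}

# Build per-node parent index lists from the base graph edges.
parent_sets <- function(g) {
  pa <- split(g$edges$from, factor(g$edges$to, levels = g$nodes))
  lapply(pa, function(p) sort(unique(p)))
}

# Core estimation engine shared by fit_common_model, permutation_null and
# semgsa. Works in covariance form: with a positive-definite sample
# covariance the group-path estimates equal node-wise least squares of
# Y_j on (pa(j), X) with an intercept; when the gene covariance is not PD
# it is shrunk first. Only the group column changes across permutations,
# so the gene-gene blocks are factorized once per node.
pathway_engine <- function(ag, data, n_rep = 0L, shrink_if_not_pd = TRUE) {
  stopifnot(inherits(ag, "augmented_graph"),
            inherits(data, "expression_dataset"))
  g <- ag$base
  miss <- setdiff(g$nodes, colnames(data$matrix))
  if (length(miss))
    stop("genes missing from the expression data: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (sum(data$group == 1L) < 2L || sum(data$group == 0L) < 2L)
    stop("both groups need at least 2 subjects")
  if (!is.null(g$bidirected) && nrow(g$bidirected) > 0)
    warning("bidirected edges in pathway '", g$name,
            "' are ignored by the fitting path")

  nodes <- g$nodes
  Y <- data$matrix[, nodes, drop = FALSE]
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  S <- crossprod(Yc) / (n - 1)
  used_shrinkage <- FALSE
  ev_min <- min(eigen((S + t(S)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min <= 1e-8) {
    if (!shrink_if_not_pd)
      stop("pathway gene covariance is not positive definite; ",
           "enable shrink_if_not_pd or remove collinear genes")
    S <- shrink_covariance(S, n)
    used_shrinkage <- TRUE
  }

  x <- data$group
  xc <- x - mean(x)
  vx <- sum(xc^2) / (n - 1)
  cX <- drop(crossprod(Yc, xc)) / (n - 1)

  pa <- parent_sets(g)
  p <- length(nodes)
  # per-node factorizations of the parent block
  node_prep <- vector("list", p)
  for (j in seq_len(p)) {
    P <- match(pa[[nodes[j]]], nodes)
    if (length(P) == 0L) { node_prep[[j]] <- list(P = integer(0)); next }
    ch <- tryCatch(chol(S[P, P, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch))
      stop("rank-deficient design for node '", nodes[j],
           "': parent genes are collinear; drop duplicated genes or ",
           "enable shrink_if_not_pd")
    w <- backsolve(ch, forwardsolve(t(ch), S[P, j]))
    node_prep[[j]] <- list(P = P, chol = ch, w = w)
  }

  solve_beta <- function(cx_node, cx_parents, prep) {
    # cx_node: scalar or n_rep-vector; cx_parents: |P| x n_rep matrix
    if (length(prep$P) == 0L) return(cx_node / vx)
    U <- backsolve(prep$chol, forwardsolve(t(prep$chol), cx_parents))
    U <- matrix(U, nrow = length(prep$P))
    num <- cx_node - colSums(cx_parents * prep$w)
    den <- pmax(vx - colSums(cx_parents * U), 1e-12)
    num / den
  }

  beta <- numeric(p)
  parent_betas <- stats::setNames(vector("list", p), nodes)
  for (j in seq_len(p)) {
    prep <- node_prep[[j]]
    if (length(prep$P) == 0L) {
      beta[j] <- cX[j] / vx
      parent_betas[[j]] <- numeric(0)
    } else {
      a <- matrix(cX[prep$P], ncol = 1)
      beta[j] <- solve_beta(cX[j], a, prep)
      u <- backsolve(prep$chol, forwardsolve(t(prep$chol), cX[prep$P]))
      parent_betas[[j]] <- stats::setNames(prep$w - u * beta[j],
                                           nodes[prep$P])
    }
  }

  null_mean <- rep(NA_real_, p)
  null_sd <- rep(NA_real_, p)
  if (n_rep > 0L) {
    XP <- vapply(seq_len(n_rep), function(r) sample(x), numeric(n))
    XPc <- XP - mean(x)
    CX <- crossprod(Yc, XPc) / (n - 1)
    for (j in seq_len(p)) {
      prep <- node_prep[[j]]
      bp <- if (length(prep$P) == 0L) CX[j, ] / vx
            else solve_beta(CX[j, ], CX[prep$P, , drop = FALSE], prep)
      null_mean[j] <- mean(bp)
      null_sd[j] <- stats::sd(bp)
    }
  }

  list(genes = nodes, beta_hat = beta, parent_betas = parent_betas,
       null_mean = null_mean, null_sd = null_sd,
       used_shrinkage = used_shrinkage, gene_cov = S)
}

#' Estimate node-wise group effects under the common-effect SEM
#'
#' For exogenous genes (no gene parents) the group path \eqn{\beta_j} is the
#' least-squares coefficient of the group indicator in a regression of the
#' gene on the group alone (a two-sample mean difference); for endogenous
#' genes it is the group coefficient adjusted for the gene's graph parents.
#' Intercepts are always included.
#'
#' @param ag an \code{augmented_graph}.
#' @param data an \code{expression_dataset} containing every pathway gene.
#' @param shrink_if_not_pd regularize a non-positive-definite pathway gene
#'   covariance before solving (default TRUE).
#' @return data frame of class \code{node_fits} with columns \code{gene},
#'   \code{beta_hat}, \code{null_mean}, \code{null_sd}, \code{p_two_sided}
#'   (the last three NA until \code{\link{permutation_null}} /
#'   \code{\link{node_pvalues}} are applied); the per-gene parent path
#'   coefficients are in \code{attr(, "parent_betas")}.
#' @export
fit_common_model <- function(ag, data, shrink_if_not_pd = TRUE) {
  eng <- pathway_engine(ag, data, n_rep = 0L,
                        shrink_if_not_pd = shrink_if_not_pd)
  out <- data.frame(gene = eng$genes, beta_hat = eng$beta_hat,
                    null_mean = NA_real_, null_sd = NA_real_,
                    p_two_sided = NA_real_, stringsAsFactors = FALSE)
  attr(out, "parent_betas") <- eng$parent_betas
  attr(out, "used_shrinkage") <- eng$used_shrinkage
  class(out) <- c("node_fits", "data.frame")
  out
}

#' Permutation null moments of the group paths
#'
#' Group labels are permuted \code{n_rep} times; each permutation re-solves
#' every node regression with the gene-gene structure held fixed (only the
#' group column changes). Returns the empirical mean and standard deviation
#' of the permuted \eqn{\beta_j} per gene.
#'
#' @param ag an \code{augmented_graph}.
#' @param data an \code{expression_dataset}.
#' @param cfg a \code{\link{fit_config}}.
#' @return data frame with columns \code{gene}, \code{null_mean},
#'   \code{null_sd}.
#' @export
permutation_null <- function(ag, data, cfg = fit_config()) {
  stopifnot(inherits(cfg, "fit_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  eng <- pathway_engine(ag, data, n_rep = cfg$n_rep,
                        shrink_if_not_pd = cfg$shrink_if_not_pd)
  data.frame(gene = eng$genes, null_mean = eng$null_mean,
             null_sd = eng$null_sd, stringsAsFactors = FALSE)
}

#' Two-sided node p-values from the moment approximation
#'
#' The permutation distribution of each group path is summarised by its
#' first two moments and the two-sided p-value read off the corresponding
#' normal distribution:
#' \eqn{p_j = 2 \Phi(-|\hat\beta_j - \mu_0| / \sigma_0)}. This moment-based
#' approximation yields accurate small p-values without a large number of
#' permutations. Values are clipped to (1e-300, 1].
#'
#' @param fits a \code{node_fits} data frame from
#'   \code{\link{fit_common_model}}.
#' @param null a data frame from \code{\link{permutation_null}}.
#' @return \code{fits} with \code{null_mean}, \code{null_sd} and
#'   \code{p_two_sided} filled in.
#' @export
node_pvalues <- function(fits, null) {
  idx <- match(fits$gene, null$gene)
  if (anyNA(idx)) stop("null moments missing for some genes")
  fits$null_mean <- null$null_mean[idx]
  fits$null_sd <- null$null_sd[idx]
  degenerate <- !is.na(fits$null_sd) & fits$null_sd == 0
  if (any(degenerate))
    warning("degenerate permutation null (sd = 0) for: ",
            paste(fits$gene[degenerate], collapse = ", "),
            "; p set to 1")
  z <- abs(fits$beta_hat - fits$null_mean) / fits$null_sd
  p <- 2 * stats::pnorm(-z)
  p[degenerate] <- 1
  fits$p_two_sided <- pmin(pmax(p, 1e-300), 1)
  fits
}
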