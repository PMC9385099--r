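#' @export
print.semgsa <- function(x, n = 10, ...) {
  cat("SEM-based gene set analysis: ", x$K, " input pathway(s), ",
      nrow(x$gsa), " analysed, n_rep = ", x$n_rep, "\n", sep = "")
  cat("Top pathways by PVAL:\n")
  top <- utils::head(x$gsa, n)
  top$pNA <- signif(top$pNA, 4); top$pNI <- signif(top$pNI, 4)
  top$PVAL <- signif(top$PVAL, 4); top$ADJP <- signif(top$ADJP, 4)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
summary.semgsa <- function(object, ...) {
  g <- object$gsa
  out <- list(
    n_pathways = object$K,
    n_analysed = nrow(g),
    n_sig_pval = sum(g$PVAL < object$alpha),
    n_sig_adjp = sum(g$ADJP < object$alpha),
    total_degs = sum(g$No.DEGs),
    pert_table = table(g$pert),
    alpha = object$alpha, method = object$method)
  class(out) <- "summary.semgsa"
  out
}

#' @export
print.summary.semgsa <- function(x, ...) {
  cat("Pathways analysed: ", x$n_analysed, " of ", x$n_pathways, "\n",
      "Significant at alpha = ", x$alpha, ": ", x$n_sig_pval,
      " (PVAL), ", x$n_sig_adjp, " (ADJP)\n",
      "Total DEGs (", x$method, "): ", x$total_degs, "\n",
      "Perturbation calls:\n", sep = "")
  print(x$pert_table)
  invisible(x)
}

#' Extract group-path coefficients
#'
#' @param object a \code{semgsa} fit.
#' @param ... unused.
#' @return named list (one element per pathway) of named numeric vectors of
#'   node-wise group effects \eqn{\hat\beta_j}.
#' @export
coef.semgsa <- function(object, ...) {
  lapply(object$fits, function(f) stats::setNames(f$beta_hat, f$gene))
}

#' Plot pathway significance
#'
#' Horizontal bars of \eqn{-\log_{10}} PVAL per pathway with the
#' significance threshold marked.
#'
#' @param x a \code{semgsa} fit.
#' @param alpha reference level (defaults to the fit's alpha).
#' @param ... passed to \code{barplot}.
#' @export
plot.semgsa <- function(x, alpha = x$alpha, ...) {
  g <- x$gsa[nrow(x$gsa):1, ]
  old <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(-log10(g$PVAL), names.arg = g$pathway, horiz = TRUE,
                    las = 1, xlab = expression(-log[10](PVAL)),
                    main = "Pathway perturbation", ...)
  graphics::abline(v = -log10(alpha), lty = 2, col = "red3")
  invisible(x)
}
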