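#' Write the gsa table as TSV
#'
#' Columns, in order: pathway, No.nodes, No.DEGs, pert, pNA, pNI, PVAL,
#' ADJP. Numbers are written at full double precision (p-values are never
#' rounded to 0).
#'
#' @param gsa the \code{gsa} data frame of a \code{semgsa} fit.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gsa <- function(gsa, path) {
  cols <- c("pathway", "No.nodes", "No.DEGs", "pert", "pNA", "pNI",
            "PVAL", "ADJP")
  stopifnot(all(cols %in% names(gsa)))
  out <- gsa[, cols, drop = FALSE]
  for (cc in c("pNA", "pNI", "PVAL", "ADJP"))
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gsa table written by \code{\link{write_gsa}}
#'
#' @param path TSV file.
#' @return data frame with the gsa columns.
#' @export
read_gsa <- function(path) {
  # na.strings empty so a literal "NA" perturbation label survives
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = character(0))
}

#' Write DEG lists as JSON
#'
#' One JSON object mapping each pathway to its (possibly empty) array of
#' DEG identifiers.
#'
#' @param degs named list of character vectors.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_degs <- function(degs, path) {
  degs <- lapply(degs, as.character)
  jsonlite::write_json(degs, path, auto_unbox = FALSE)
  invisible(path)
}

#' Write all outputs of a gene set analysis
#'
#' Writes \code{gsa.tsv}, \code{degs.json} and \code{manifest.json}
#' (configuration and seed) into \code{outdir}.
#'
#' @param fit a \code{semgsa} object.
#' @param outdir output directory (created if missing).
#' @return \code{outdir}, invisibly.
#' @export
write_outputs <- function(fit, outdir) {
  stopifnot(inherits(fit, "semgsa"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_gsa(fit$gsa, file.path(outdir, "gsa.tsv"))
  write_degs(fit$DEG, file.path(outdir, "degs.json"))
  manifest <- list(K = fit$K, method = fit$method, alpha = fit$alpha,
                   n_rep = fit$n_rep,
                   seed = if (is.null(fit$seed)) NA else fit$seed)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Emit a small packaged toy fixture
#'
#' Writes a reproducible synthetic fixture for examples and smoke tests:
#' 3 signed pathway graphs as edge lists under \code{graphs/}, an
#' expression TSV for 40 subjects with a planted shift in the first
#' pathway, and a group file.
#'
#' @param outdir output directory.
#' @param seed integer seed (default 42).
#' @return \code{outdir}, invisibly.
#' @export
emit_fixtures <- function(outdir, seed = 42) {
  dir.create(file.path(outdir, "graphs"), showWarnings = FALSE,
             recursive = TRUE)
  gs <- simulate_pathways(n_pathways = 3, size_range = c(10, 14),
                          seed = seed)
  for (g in gs)
    write_pathway(g, file.path(outdir, "graphs", paste0(g$name, ".tsv")))
  genes <- sort(unique(unlist(lapply(gs, function(g) g$nodes))))
  data <- generate_base_data(genes, n_cases = 20, n_controls = 20,
                             corr = "independent")
  aff <- data.frame(gene = gs[[1]]$nodes,
                    sign = gene_signs(gs[[1]], gs[[1]]$nodes))
  data <- inject_signal(data, aff, 0.8)
  df <- data.frame(subject = rownames(data$matrix), data$matrix,
                   check.names = FALSE)
  utils::write.table(df, file.path(outdir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(as.character(data$group), file.path(outdir, "group.txt"))
  invisible(outdir)
}
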