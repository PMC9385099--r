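#' Expression dataset with aligned binary group labels
#'
#' @param x numeric matrix, subjects in rows, genes in columns; column
#'   names are gene identifiers, row names subject identifiers.
#' @param group vector of 0/1 labels (1 = case, 0 = control), one per
#'   subject.
#' @return object of class \code{expression_dataset} with fields
#'   \code{matrix} and \code{group}.
#' @export
expression_dataset <- function(x, group) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (is.null(colnames(x))) stop("expression matrix must have gene column names")
  if (anyDuplicated(colnames(x))) stop("duplicate gene identifiers")
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  group <- as.integer(group)
  if (length(group) != nrow(x))
    stop("group vector length (", length(group),
         ") does not match subject count (", nrow(x), ")")
  if (!all(group %in% c(0L, 1L))) stop("group labels must be 0 or 1")
  if (sum(group == 1L) == 0L || sum(group == 0L) == 0L)
    stop("both groups must be nonempty")
  structure(list(matrix = x, group = group), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$matrix), " subjects x ",
      ncol(x$matrix), " genes (", sum(x$group == 1L), " cases, ",
      sum(x$group == 0L), " controls)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and group labels from disk
#'
#' The data file is TSV or CSV (chosen from the file extension, ".csv" means
#' comma) with a header of gene identifiers and the subject identifier in
#' the first column. The group file holds one label (0/1) per line, aligned
#' to the data rows, or two whitespace-separated columns
#' \code{subject label}, matched to the data by subject identifier.
#'
#' @param data_file path to the expression table.
#' @param group_file path to the group label file.
#' @return an \code{expression_dataset}.
#' @export
read_expression <- function(data_file, group_file) {
  if (!file.exists(data_file)) stop("data file not found: ", data_file)
  if (!file.exists(group_file)) stop("group file not found: ", group_file)
  sep <- if (grepl("\\.csv$", data_file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(data_file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  subjects <- as.character(df[[1]])
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- subjects
  gl <- utils::read.table(group_file, header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(gl) == 1L) {
    group <- gl[[1]]
  } else {
    idx <- match(subjects, as.character(gl[[1]]))
    if (anyNA(idx))
      stop("group file is missing subjects: ",
           paste(subjects[is.na(idx)], collapse = ", "))
    group <- gl[[2]][idx]
  }
  expression_dataset(x, group)
}
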