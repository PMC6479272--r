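#' Expression matrix container
#'
#' A samples x genes numeric matrix of relative expression values carrying a
#' scale flag: `"linear"` (relative quantities, strictly positive where
#' present) or `"log2"`. Missing entries (`NA`) are allowed before imputation.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   genes in columns (colnames = gene symbols).
#' @param scale `"linear"` or `"log2"`.
#' @return An `expr_matrix`: the matrix with a `scale` attribute.
#' @export
expression_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("gene (column) names are required")
  if (is.null(rownames(values))) stop("sample (row) names are required")
  if (anyDuplicated(colnames(values))) stop("gene ids must be unique")
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique")
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (scale == "linear" && any(values <= 0, na.rm = TRUE))
    stop("linear-scale expression values must be strictly positive")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix (%s scale): %d samples x %d genes, %d missing\n",
              expr_scale(x), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Scale flag of an expression matrix
#' @param x an [expression_matrix].
#' @return `"linear"` or `"log2"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("not an expression matrix: no scale attribute")
  s
}

as_plain_matrix <- function(x) {
  attr(x, "scale") <- NULL
  class(x) <- setdiff(class(x), "expr_matrix")
  unclass(x)
}

#' Read / write expression matrices as TSV
#'
#' TSV layout: first column `sample_id`, remaining columns one per gene;
#' missing values encoded as empty fields or `NA`.
#'
#' @param path file path.
#' @param scale scale flag recorded on the matrix read.
#' @return `read_expression_tsv` returns an [expression_matrix].
#' @export
read_expression_tsv <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  expression_matrix(m, scale = scale)
}

#' @param x an [expression_matrix].
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as_plain_matrix(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
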