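#' Signature expression profile
#'
#' The per-gene median of the log2 expression values across the cohort —
#' the profile that is aligned against compendium conditions.
#'
#' @param expr a log2-scale [expression_matrix].
#' @return Named numeric vector of per-gene medians; genes with no observed
#'   value are excluded with a warning.
#' @export
signature_profile <- function(expr) {
  if (expr_scale(expr) != "log2") stop("profile is computed on log2 scale")
  x <- as_plain_matrix(expr)
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning("gene(s) with no observed values excluded: ",
            paste(colnames(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  apply(x, 2, median, na.rm = TRUE)
}

#' Expression compendium container
#'
#' A conditions x genes matrix of log2 expression profiles with per-condition
#' array counts; conditions with fewer arrays than the floor are excluded
#' (flagged in the result).
#'
#' @param profiles numeric matrix, conditions in rows (rownames = condition
#'   labels), genes in columns.
#' @param n_arrays integer vector of arrays per condition.
#' @param n_floor minimum arrays for a condition to be eligible.
#' @return A `compendium` object.
#' @export
compendium <- function(profiles, n_arrays, n_floor = 15) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) stop("condition labels required")
  if (length(n_arrays) != nrow(profiles))
    stop("n_arrays must have one entry per condition")
  keep <- n_arrays >= n_floor
  structure(list(profiles = profiles, n_arrays = n_arrays,
                 eligible = keep, n_floor = n_floor,
                 excluded_small = rownames(profiles)[!keep]),
            class = "compendium")
}

#' Read a compendium from TSV
#'
#' Layout: first column `condition`, second column `n_arrays`, remaining
#' columns one per gene.
#'
#' @param path TSV path.
#' @param n_floor minimum arrays per condition.
#' @return A [compendium].
#' @export
read_compendium_tsv <- function(path, n_floor = 15) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  compendium(m, as.integer(df[[2]]), n_floor = n_floor)
}

#' Rank compendium conditions by similarity to a signature profile
#'
#' Computes the Pearson correlation between the signature profile and each
#' eligible condition over their shared genes, and the relative-similarity
#' index `RS = r / mean(r over included conditions)` — a positive rescaling
#' of `r`, so the RS ranking equals the correlation ranking and `RS > 1`
#' flags above-average resemblance. Conditions sharing fewer than
#' `min_shared` genes with the profile are excluded and logged.
#'
#' @param profile named numeric vector (see [signature_profile()]).
#' @param comp a [compendium].
#' @param top_k number of top conditions returned.
#' @param min_shared minimum shared genes per condition.
#' @return A `similarity_ranking`: data frame `table` (condition, r,
#'   rel_similarity, rank, n_shared) restricted to the top `top_k`, plus
#'   `full` (all included conditions) and `excluded`.
#' @export
rank_conditions <- function(profile, comp, top_k = 10, min_shared = 3) {
  stopifnot(inherits(comp, "compendium"))
  prof_genes <- names(profile)
  rows <- lapply(rownames(comp$profiles)[comp$eligible], function(cond) {
    v <- comp$profiles[cond, ]
    shared <- intersect(prof_genes, names(v)[!is.na(v)])
    if (length(shared) < min_shared) return(NULL)
    data.frame(condition = cond,
               r = cor(profile[shared], v[shared]),
               n_shared = length(shared), stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  excluded <- rownames(comp$profiles)[comp$eligible][!keep]
  tab <- do.call(rbind, rows[keep])
  if (is.null(tab) || !nrow(tab)) stop("no condition shares enough genes")
  tab$rel_similarity <- tab$r / mean(tab$r)
  # ordering by r equals ordering by RS whenever mean(r) > 0, and stays
  # well-defined when the mean correlation is not positive
  tab <- tab[order(-tab$r), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = utils::head(tab, top_k), full = tab,
                 excluded = c(excluded, comp$excluded_small)),
            class = "similarity_ranking")
}

#' @export
print.similarity_ranking <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Top co-expressed genes of a target gene
#'
#' Pearson correlation of the target gene's column against every other
#' column of a samples x genes matrix, sorted by descending correlation.
#'
#' @param mat samples x genes numeric matrix with at least 3 samples.
#' @param target target gene (column name).
#' @param n list length.
#' @return A `coexpression_list`: data frame (`gene`, `r`) of the top `n`
#'   co-expressed genes (target excluded), with the target as attribute.
#' @export
coexpression_top_n <- function(mat, target, n = 200) {
  mat <- as.matrix(mat)
  if (!target %in% colnames(mat)) stop("target gene absent: ", target)
  if (nrow(mat) < 3) stop("at least 3 samples required")
  tv <- mat[, target]
  if (sd(tv) == 0) stop("target gene has constant expression")
  others <- setdiff(colnames(mat), target)
  r <- suppressWarnings(as.vector(cor(tv, mat[, others, drop = FALSE])))
  names(r) <- others
  r <- r[!is.na(r)]
  r <- sort(r, decreasing = TRUE)
  out <- data.frame(gene = names(r), r = unname(r),
                    stringsAsFactors = FALSE)[seq_len(min(n, length(r))), ]
  rownames(out) <- NULL
  structure(out, target = target, class = c("coexpression_list",
                                            class(out)))
}

#' Overlap of two gene lists
#'
#' Case-normalized intersection of gene symbols; duplicate entries (e.g.
#' multiple probes collapsing to one gene) count once. Non-annotated probes
#' compare by their probe identifier like any other string.
#'
#' @param list_a,list_b character vectors of gene names (or
#'   `coexpression_list` objects, whose `gene` column is used).
#' @return List with `genes` (sorted intersection) and `count`.
#' @export
list_overlap <- function(list_a, list_b) {
  norm <- function(v) {
    if (inherits(v, "coexpression_list")) v <- v$gene
    unique(toupper(trimws(as.character(v))))
  }
  genes <- sort(intersect(norm(list_a), norm(list_b)))
  list(genes = genes, count = length(genes))
}
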